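test_that("a fresh ensemble starts at the origin, growing, with flow at v0", {
  p <- params_with()
  ens <- init_ensemble(100, p)
  expect_length(ens$r, 100)
  expect_true(all(ens$r == 0))
  expect_true(all(ens$growing))
  expect_identical(ens$vr, p$actin$v0)
  expect_identical(leading_edge_fraction(ens, p$geom), 0)
  expect_length(init_ensemble(1, p)$r, 1)
  expect_error(init_ensemble(0, p), "n_mt")
})

test_that("leading-edge fraction counts tips strictly past the cutoff", {
  geom <- geometry(R = 10)
  expect_equal(leading_edge_fraction(ensemble_at(c(8, 5, 9, 1)), geom), 0.5)
  expect_equal(leading_edge_fraction(ensemble_at(rep(0, 5)), geom), 0)
  expect_equal(leading_edge_fraction(ensemble_at(rep(10, 5)), geom), 1)
  # a tip exactly on the 75% line is not counted (strict inequality)
  expect_equal(leading_edge_fraction(ensemble_at(c(7.5, 8)), geom), 0.5)
  expect_error(leading_edge_fraction(ensemble_at(numeric(0)), geom), "empty")
})

test_that("an uncoupled growing tip advances by pure polymerization", {
  p <- gc_params(mt = mt_params(f_cat = 1e-9), actin = actin_params())
  cfg <- sim_config(dt = 0.01, t_total = 1, burn_in = 0.5, n_mt = 1)
  set.seed(1)
  ens <- step_ensemble(init_ensemble(1, p), pr = 0, p, cfg)
  expect_equal(ens$r, 0.06)
  expect_true(ens$growing)
})

test_that("mean tip drift matches the effective speeds in both coupling modes", {
  # switching suppressed; start mid-domain so boundaries are never touched
  p <- gc_params(mt = mt_params(f_cat = 1e-9, f_res = 1e-9),
                 actin = actin_params(v0 = 4))
  pr <- 0.6
  n_steps <- 40L
  for (mode in c("mean", "bernoulli")) {
    cfg <- sim_config(dt = 0.005, t_total = 1, burn_in = 0.5, n_mt = 2000,
                      coupling_mode = mode)
    set.seed(42)
    ens <- ensemble_at(rep(5, 2000), vr = 4)
    # beta = 0 keeps vr fixed at v0 = 4 throughout
    for (s in seq_len(n_steps)) ens <- step_ensemble(ens, pr, p, cfg)
    drift <- mean(ens$r - 5) / (n_steps * cfg$dt)
    expected <- p$mt$v_plus - pr * 4
    if (mode == "mean") {
      expect_equal(drift, expected, tolerance = 1e-12)
    } else {
      se <- stats::sd(ens$r - 5) / sqrt(2000) / (n_steps * cfg$dt)
      expect_lt(abs(drift - expected), 3 * se)
    }
  }
})

test_that("compiled and pure-R engines are bit-identical under a shared seed", {
  p <- params_with(A = 0.9, beta = 0.1)
  for (mode in c("mean", "bernoulli")) {
    cfg <- fast_cfg(t_total = 2, burn_in = 1, n_mt = 50, record_stride = 5,
                    coupling_mode = mode)
    a <- simulate_angle(30, p, cfg, engine = "compiled")
    b <- simulate_angle(30, p, cfg, engine = "r")
    expect_identical(a$p, b$p)
    expect_identical(a$vr, b$vr)
    expect_identical(a$r, b$r)
    expect_identical(a$growing, b$growing)
  }
})

test_that("runs are deterministic in the master seed", {
  p <- params_with(A = 0.9, beta = 0.1)
  cfg <- fast_cfg(t_total = 3, burn_in = 1, n_mt = 60)
  a <- simulate_angle(50, p, cfg)
  b <- simulate_angle(50, p, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_angle(50, p, cfg, seed = 999)
  expect_false(identical(a$p, c$p))
})

test_that("MT count is conserved, tips stay in-domain, and vr tracks the force balance", {
  set.seed(3)
  for (k in 1:4) {
    p <- params_with(A = sample(c(0, 0.5, 0.9), 1), beta = runif(1, 0, 2))
    cfg <- fast_cfg(t_total = 4, burn_in = 1, n_mt = 80,
                    seed = sample.int(1e6, 1),
                    coupling_mode = sample(c("mean", "bernoulli"), 1))
    ts <- simulate_angle(runif(1, 0, 180), p, cfg)
    expect_length(ts$r, cfg$n_mt)
    expect_true(all(ts$r >= 0 & ts$r <= p$geom$R))
    # recorded vr is exactly the adhesion force balance evaluated at the recorded p
    expect_identical(ts$vr, p$actin$v0 / (1 + p$actin$beta * ts$p))
  }
})

test_that("with beta = 0 retrograde flow never deviates from v0", {
  p <- params_with(A = 0.9, beta = 0)
  cfg <- fast_cfg(t_total = 5, burn_in = 2, n_mt = 100)
  for (th in c(0, 90, 180)) {
    ts <- simulate_angle(th, p, cfg)
    expect_identical(ts$vr, rep(p$actin$v0, length(ts$vr)))
  }
})

test_that("steady-state summaries average the post-burn-in window", {
  cfg <- fast_cfg(t_total = 10, burn_in = 5)
  tgrid <- seq(0, 10, by = 0.025)
  ts <- series_of(tgrid, p = rep(0.5, length(tgrid)), vr = rep(4, length(tgrid)),
                  cfg = cfg)
  ss <- steady_state_summary(ts, cfg)
  expect_equal(ss$p_mean, 0.5)
  expect_equal(ss$p_se, 0)
  expect_equal(ss$vcell_mean, 5 - 4)
  # a beta = 0 run averages to exactly v0 and vp - v0
  p0 <- params_with(beta = 0)
  ts0 <- simulate_angle(90, p0, fast_cfg())
  ss0 <- steady_state_summary(ts0)
  expect_equal(ss0$vr_mean, 5)
  expect_equal(ss0$vcell_mean, 0)
  # too few post-burn-in samples is an error
  short <- series_of(seq(0, 10, by = 1), p = rep(0, 11), vr = rep(5, 11), cfg = cfg)
  expect_error(steady_state_summary(short, cfg), "samples")
})

test_that("mean and bernoulli coupling agree statistically on the steady state", {
  p <- params_with(A = 0, beta = 0.1)
  run <- function(mode) {
    cfg <- sim_config(t_total = 40, burn_in = 10, n_mt = 400,
                      coupling_mode = mode, seed = 5)
    steady_state_summary(simulate_angle(90, p, cfg))
  }
  a <- run("mean"); b <- run("bernoulli")
  se <- sqrt(a$p_se^2 + b$p_se^2)
  expect_lt(abs(a$p_mean - b$p_mean), 3 * se)
})

test_that("the net protrusion vector sums local protrusion vectors", {
  th <- seq(0, 180, by = 10)
  expect_equal(net_protrusion_angle(rep(1, length(th)), th), 90)
  expect_equal(net_protrusion_angle(c(1, rep(0, 18)), th), 0)
  v <- rep(0, 19); v[1] <- 1; v[10] <- 1   # theta = 0 and theta = 90
  expect_equal(net_protrusion_angle(v, th), 45)
  expect_true(is.na(net_protrusion_angle(rep(0, 19), th, eps = 1e-12)))
})

test_that("growth cone profiles are congruent with the angle grid", {
  p <- params_with(A = 0.9, beta = 0.1, theta_grid = c(0, 45, 90, 135, 180))
  cfg <- fast_cfg(t_total = 8, burn_in = 3, n_mt = 60, record_stride = 2)
  prof <- simulate_growth_cone(p, cfg)
  expect_s3_class(prof, "gc_profile")
  expect_identical(prof$theta_deg, c(0, 45, 90, 135, 180))
  expect_true(all(prof$p_mean >= 0 & prof$p_mean <= 1))
  tp <- attr(prof, "theta_p")
  expect_true(is.na(tp) || (tp >= 0 && tp <= 180))
  # independent per-angle substreams: a single angle rerun alone matches
  ts <- simulate_angle(90, p, cfg, seed = gcsteer:::angle_seed(cfg$seed, 90))
  expect_equal(steady_state_summary(ts, cfg)$p_mean,
               prof$p_mean[prof$theta_deg == 90])
})

test_that("a single-point sweep reproduces a direct growth cone run", {
  p <- params_with(A = 0.9, beta = 0.1, theta_grid = c(0, 90, 180))
  cfg <- fast_cfg(t_total = 6, burn_in = 2, n_mt = 40, record_stride = 2)
  sw <- sweep_protrusion(p, cfg)
  expect_identical(nrow(sw), 1L)
  prof <- simulate_growth_cone(p, cfg)
  expect_equal(sw$theta_p, attr(prof, "theta_p"))
  sw2 <- sweep_protrusion(p, cfg, A_values = c(0, 0.9), beta_values = c(0.1, 1))
  expect_identical(nrow(sw2), 4L)
  expect_identical(sw2$A, c(0, 0, 0.9, 0.9))
  expect_error(sweep_protrusion(p, cfg, beta_values = numeric(0)), "non-empty")
})
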