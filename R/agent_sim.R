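#' Initialize a microtubule ensemble at one angular coordinate
#'
#' All MTs start at the origin of the radial slice (`r = 0`, the central
#' domain boundary) in the growing phase, and the retrograde flow speed is
#' initialized to `v0` since no MT is yet at the leading edge.
#'
#' @param n_mt number of MT agents, `>= 1`.
#' @param params [gc_params()] bundle.
#' @param theta_deg angular coordinate of the slice, degrees (carried as
#'   metadata).
#'
#' @return An object of class `ensemble_state`: list with elements `r`
#'   (tip radial positions, um), `growing` (logical phase vector), `vr`
#'   (current retrograde flow speed, um/min), `theta_deg`, `t` (time, min).
#' @examples
#' ens <- init_ensemble(10, gc_params())
#' leading_edge_fraction(ens, geometry())
#' @export
init_ensemble <- function(n_mt, params, theta_deg = 90) {
  n_mt <- as.integer(n_mt)
  if (is.na(n_mt) || n_mt < 1L) stop("n_mt must be >= 1", call. = FALSE)
  structure(list(r = numeric(n_mt), growing = rep(TRUE, n_mt),
                 vr = params$actin$v0, theta_deg = theta_deg, t = 0),
            class = "ensemble_state")
}

#' Fraction of MTs past the leading-edge line
#'
#' Counts tips with `r > leading_edge_cutoff * R` (strict inequality) and
#' divides by the ensemble size.
#'
#' @param ens [init_ensemble()] state.
#' @param geom [geometry()].
#' @return Fraction in `[0, 1]`.
#' @export
leading_edge_fraction <- function(ens, geom) {
  if (length(ens$r) == 0L) stop("empty ensemble", call. = FALSE)
  mean(ens$r > geom$leading_edge_cutoff * geom$R)
}

#' Advance an MT ensemble by one time step (reference implementation)
#'
#' Each MT independently switches growing -> shrinking with probability
#' `f_cat * dt` and shrinking -> growing with probability `f_res * dt`; a
#' growing tip then advances by `(v_plus - c * vr) * dt` and a shrinking tip
#' retreats by `(v_minus + c * vr) * dt`, where the coupling indicator `c`
#' equals `pr` in `"mean"` mode and is a fresh Bernoulli(`pr`) draw per MT in
#' `"bernoulli"` mode.  A tip reaching `R` is clamped there and forced into
#' catastrophe (the membrane is a barrier); a shrinking tip reaching 0 is
#' clamped and switched to growing (regrowth from the central domain, so the
#' MT count is conserved).  Finally `p` is recomputed and `vr` updated to the
#' algebraic force balance `v0 / (1 + beta * p)`.
#'
#' This pure-R stepper defines the scheme; [simulate_angle()] runs the same
#' scheme in compiled code and reproduces it bit-for-bit under a shared seed.
#'
#' @param ens [init_ensemble()] state.
#' @param pr coupling probability for this slice (depends only on the
#'   angle), in `[0, 1]`.
#' @param params [gc_params()] bundle.
#' @param cfg [sim_config()].
#' @return The updated `ensemble_state`.
#' @export
step_ensemble <- function(ens, pr, params, cfg) {
  mt <- params$mt; actin <- params$actin; geom <- params$geom
  dt <- cfg$dt
  n <- length(ens$r)
  grow <- ens$growing
  vr <- ens$vr

  u <- runif(n)
  sw <- ifelse(grow, u < mt$f_cat * dt, u < mt$f_res * dt)
  grow <- xor(grow, sw)

  c_ind <- if (cfg$coupling_mode == "bernoulli") as.numeric(runif(n) < pr) else pr
  r <- ens$r + ifelse(grow, (mt$v_plus - c_ind * vr) * dt,
                      -(mt$v_minus + c_ind * vr) * dt)

  hi <- r >= geom$R
  r[hi] <- geom$R
  grow[hi] <- FALSE
  lo <- !hi & r <= 0
  r[lo] <- 0
  grow[lo & !grow] <- TRUE

  p <- mean(r > geom$leading_edge_cutoff * geom$R)
  structure(list(r = r, growing = grow,
                 vr = actin$v0 / (1 + actin$beta * p),
                 theta_deg = ens$theta_deg, t = ens$t + dt),
            class = "ensemble_state")
}

# Deterministic per-angle RNG substream: depends on the master seed and the
# angle value only, so results are independent of grid order and of the
# other angles. Kept below 2^31.
angle_seed <- function(seed, theta_deg) {
  as.integer((as.numeric(seed) %% 2147483629 +
                round(theta_deg * 1000) * 40009) %% 2147483629)
}

point_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * (i - 1)) %% 2147483629)
}

#' Simulate one angular slice of the growth cone
#'
#' Runs a stochastic MT ensemble at fixed coupling probability
#' `pr = coupling_probability(theta_deg, grad)` for `t_total / dt` steps,
#' with the retrograde-flow feedback updated every step, recording the
#' leading-edge fraction `p` and flow speed `vr` every `record_stride` steps
#' (including the initial state at `t = 0`).  Deterministic given `seed`.
#'
#' @param theta_deg angle in degrees, in `[0, 180]`.
#' @param params [gc_params()] bundle.
#' @param cfg [sim_config()].
#' @param seed RNG seed for this slice; defaults to the master `cfg$seed`.
#' @param engine `"compiled"` (default) runs the loop in C++; `"r"` loops
#'   [step_ensemble()] in R.  Both consume the RNG identically and give
#'   bit-identical results.
#'
#' @return An object of class `angle_series`: list with `theta_deg`, `pr`,
#'   recorded vectors `t`, `p`, `vr`, the final ensemble `r` / `growing`
#'   vectors, and the `params` / `cfg` used.
#' @examples
#' p <- gc_params(actin = actin_params(beta = 0.1),
#'                grad = gradient_params(A = 0.9))
#' cfg <- sim_config(t_total = 5, burn_in = 1, n_mt = 50)
#' ts <- simulate_angle(0, p, cfg)
#' head(as.data.frame(ts))
#' @export
simulate_angle <- function(theta_deg, params, cfg, seed = cfg$seed,
                           engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  stop_on_violations(check_sim_config(cfg, params))
  pr <- coupling_probability(theta_deg, params$grad)
  n_steps <- round(cfg$t_total / cfg$dt)

  set.seed(seed)
  ens <- init_ensemble(cfg$n_mt, params, theta_deg)

  if (engine == "compiled") {
    out <- .sim_angle_kernel(ens$r, ens$growing, ens$vr,
                             params$geom$R,
                             params$geom$leading_edge_cutoff * params$geom$R,
                             pr, params$mt$v_plus, params$mt$v_minus,
                             params$mt$f_cat, params$mt$f_res,
                             params$actin$v0, params$actin$beta,
                             cfg$dt, n_steps, cfg$record_stride,
                             cfg$coupling_mode == "bernoulli")
    t_rec <- out$t; p_rec <- out$p; vr_rec <- out$vr
    r_fin <- out$r; g_fin <- out$growing
  } else {
    n_rec <- n_steps %/% cfg$record_stride + 1L
    t_rec <- p_rec <- vr_rec <- numeric(n_rec)
    k <- 1L
    t_rec[k] <- 0
    p_rec[k] <- leading_edge_fraction(ens, params$geom)
    vr_rec[k] <- ens$vr
    for (s in seq_len(n_steps)) {
      ens <- step_ensemble(ens, pr, params, cfg)
      if (s %% cfg$record_stride == 0L) {
        k <- k + 1L
        t_rec[k] <- s * cfg$dt
        p_rec[k] <- leading_edge_fraction(ens, params$geom)
        vr_rec[k] <- ens$vr
      }
    }
    r_fin <- ens$r; g_fin <- ens$growing
  }

  structure(list(theta_deg = theta_deg, pr = pr,
                 t = t_rec, p = p_rec, vr = vr_rec,
                 r = r_fin, growing = g_fin, seed = seed,
                 params = params, cfg = cfg),
            class = "angle_series")
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(theta_deg = x$theta_deg, t = x$t, p = x$p, vr = x$vr)
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("MT ensemble time series at theta = %g deg (pr = %.3f)\n",
              x$theta_deg, x$pr))
  cat(sprintf("  %d MTs, %d samples over %g min; final p = %.3f, vr = %.3f um/min\n",
              length(x$r), length(x$t), max(x$t),
              x$p[length(x$p)], x$vr[length(x$vr)]))
  invisible(x)
}

# Flyvbjerg-Petersen blocking: average adjacent pairs repeatedly and take
# the largest SE among levels with enough blocks, so autocorrelation does
# not bias the naive SE downward.
block_se <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  best <- stats::sd(x) / sqrt(n)
  while (length(x) >= 32L) {
    if (length(x) %% 2L == 1L) x <- x[-1L]
    x <- (x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]) / 2
    m <- length(x)
    if (m >= 16L) best <- max(best, stats::sd(x) / sqrt(m))
  }
  best
}

#' Steady-state averages of an angular time series
#'
#' Time averages of `p` and `vr` over `t > burn_in`, the protrusion speed
#' `vcell = vp - vr_mean`, and standard errors from an autocorrelation-aware
#' blocking estimator (adjacent-pair block averaging, taking the largest SE
#' across blocking levels).
#'
#' @param ts [simulate_angle()] result.
#' @param cfg [sim_config()]; defaults to the one stored in `ts`.
#' @param min_samples smallest acceptable number of post-burn-in samples.
#' @return A one-row data.frame with `theta_deg`, `p_mean`, `p_se`,
#'   `vr_mean`, `vr_se`, `vcell_mean`, `vcell_se`, `n_samples`.
#' @export
steady_state_summary <- function(ts, cfg = ts$cfg, min_samples = 100L) {
  keep <- ts$t > cfg$burn_in
  if (sum(keep) < min_samples)
    stop(sprintf("only %d samples after burn-in (need >= %d); extend t_total or record more densely",
                 sum(keep), min_samples), call. = FALSE)
  p <- ts$p[keep]; vr <- ts$vr[keep]
  vp <- ts$params$actin$vp
  data.frame(theta_deg = ts$theta_deg,
             p_mean = mean(p), p_se = block_se(p),
             vr_mean = mean(vr), vr_se = block_se(vr),
             vcell_mean = vp - mean(vr), vcell_se = block_se(vr),
             n_samples = sum(keep))
}

#' Net protrusion angle from local protrusion vectors
#'
#' The local protrusion vector at angle `theta` has components
#' `(vcell * cos(theta), vcell * sin(theta))`, with equal weight per angle;
#' the net protrusion angle `theta_p` is the polar angle of their sum.
#' `theta_p = 0` is alignment with the cue gradient, `theta_p = 90` the
#' original growth axis.  When the summed vector is shorter than `eps` the
#' direction is undefined and `NA` is returned (e.g. `beta = 0` under the
#' treadmilling condition, where every local `vcell` is 0 on average).
#'
#' @param x a `gc_profile` from [simulate_growth_cone()], or a numeric
#'   vector of local protrusion speeds.
#' @param ... passed to methods.
#' @return Angle in degrees in `[0, 180]` for profiles of non-negative
#'   `vcell`, or `NA_real_` when undefined.
#' @examples
#' net_protrusion_angle(c(1, 1), theta_deg = c(0, 90))  # 45
#' @export
net_protrusion_angle <- function(x, ...) UseMethod("net_protrusion_angle")

#' @rdname net_protrusion_angle
#' @param theta_deg angles (degrees) matching `x` when `x` is a vector.
#' @param eps magnitude below which the direction is reported undefined.
#' @export
net_protrusion_angle.default <- function(x, theta_deg, eps = 0, ...) {
  stopifnot(length(x) == length(theta_deg))
  sx <- sum(x * cospi(theta_deg / 180))
  sy <- sum(x * sinpi(theta_deg / 180))
  mag <- sqrt(sx^2 + sy^2)
  if (mag <= eps) return(NA_real_)
  atan2(sy, sx) * 180 / pi
}

#' @rdname net_protrusion_angle
#' @export
net_protrusion_angle.gc_profile <- function(x, ...) {
  params <- attr(x, "params")
  eps <- 1e-9 * params$actin$v0 * nrow(x)
  net_protrusion_angle(x$vcell_mean, x$theta_deg, eps = eps)
}

#' Simulate the whole growth cone and summarise its steady state
#'
#' Runs an independent MT ensemble at every angle of `geom$theta_grid`
#' (each on its own RNG substream derived from the master seed, so results
#' do not depend on grid order), averages each over the post-burn-in window,
#' and computes the net protrusion angle from the vector sum of local
#' protrusion vectors.
#'
#' @param params [gc_params()] bundle.
#' @param cfg [sim_config()].
#' @return An object of class `gc_profile`: a data.frame with one row per
#'   angle (`theta_deg`, `pr`, `p_mean`, `p_se`, `vr_mean`, `vr_se`,
#'   `vcell_mean`, `vcell_se`, `n_samples`) and attributes `theta_p` (net
#'   protrusion angle, degrees, `NA` if undefined), `net_magnitude`,
#'   `params`, `cfg`.
#' @examples
#' p <- gc_params(actin = actin_params(beta = 0.1),
#'                grad = gradient_params(A = 0.9),
#'                geom = geometry(theta_grid = c(0, 90, 180)))
#' cfg <- sim_config(t_total = 4, burn_in = 2, n_mt = 50, record_stride = 2)
#' prof <- simulate_growth_cone(p, cfg)
#' attr(prof, "theta_p")
#' @export
simulate_growth_cone <- function(params, cfg) {
  stop_on_violations(check_sim_config(cfg, params))
  rows <- lapply(params$geom$theta_grid, function(th) {
    ts <- simulate_angle(th, params, cfg, seed = angle_seed(cfg$seed, th))
    cbind(steady_state_summary(ts, cfg),
          pr = ts$pr)[, c("theta_deg", "pr", "p_mean", "p_se", "vr_mean",
                          "vr_se", "vcell_mean", "vcell_se", "n_samples")]
  })
  prof <- do.call(rbind, rows)
  class(prof) <- c("gc_profile", "data.frame")
  attr(prof, "params") <- params
  attr(prof, "cfg") <- cfg
  sx <- sum(prof$vcell_mean * cospi(prof$theta_deg / 180))
  sy <- sum(prof$vcell_mean * sinpi(prof$theta_deg / 180))
  attr(prof, "net_magnitude") <- sqrt(sx^2 + sy^2)
  attr(prof, "theta_p") <- net_protrusion_angle(prof)
  prof
}

#' @export
print.gc_profile <- function(x, ...) {
  tp <- attr(x, "theta_p")
  cat(sprintf("Growth cone steady-state profile (%d angles)\n", nrow(x)))
  cat(sprintf("  net protrusion angle theta_p = %s deg\n",
              if (is.na(tp)) "undefined" else sprintf("%.2f", tp)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Sweep gradient steepness and adhesion sensitivity
#'
#' Re-runs [simulate_growth_cone()] on a grid of `A` and/or `beta` values
#' (all other parameters from `params`), each grid point on a reproducible
#' seed derived from the master seed; a single-point grid reproduces a
#' direct [simulate_growth_cone()] call with the same seed.
#'
#' @param params [gc_params()] template.
#' @param cfg [sim_config()].
#' @param A_values gradient steepness values; default the template's `A`.
#' @param beta_values adhesion sensitivity values; default the template's
#'   `beta`.
#' @return A long-format data.frame with one row per grid point: `A`,
#'   `beta`, `seed`, `theta_p`, `net_magnitude`, `p_lead_mean` (leading-edge
#'   fraction averaged over angles), `vcell_max`.
#' @export
sweep_protrusion <- function(params, cfg, A_values = NULL, beta_values = NULL) {
  if (is.null(A_values)) A_values <- params$grad$A
  if (is.null(beta_values)) beta_values <- params$actin$beta
  if (length(A_values) == 0L || length(beta_values) == 0L)
    stop("sweep axes must be non-empty", call. = FALSE)
  grid <- expand.grid(beta = beta_values, A = A_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pa <- params$actin; pa$beta <- grid$beta[i]
    pg <- params$grad; pg$A <- grid$A[i]
    p_i <- gc_params(params$mt, pa, pg, params$geom)
    cfg_i <- cfg; cfg_i$seed <- point_seed(cfg$seed, i)
    prof <- simulate_growth_cone(p_i, cfg_i)
    data.frame(A = grid$A[i], beta = grid$beta[i], seed = cfg_i$seed,
               theta_p = attr(prof, "theta_p"),
               net_magnitude = attr(prof, "net_magnitude"),
               p_lead_mean = mean(prof$p_mean),
               vcell_max = max(prof$vcell_mean))
  })
  do.call(rbind, rows)
}
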