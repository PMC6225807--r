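#' Analytic steady-state length constant of the two-state tip model
#'
#' In the bounded regime the steady-state tip-position density decays
#' exponentially with length constant
#' `lambda = 1 / (f_cat / v_g - f_res / v_s)`, where `v_g = v_plus - pr*vr`
#' and `v_s = v_minus + pr*vr` are the effective growth and shrink speeds
#' under retrograde drift.  In the unbounded (or marginal) regime no finite
#' length scale exists and `Inf` is returned.  The degenerate bounded case
#' `v_g <= 0` (mean tip drift retrograde in both phases, all mass collapsing
#' to the origin) returns 0.
#'
#' @param mt [mt_params()].
#' @param pr coupling probability in `[0, 1]`.
#' @param vr retrograde flow speed, um/min.
#' @return Length constant in um; `Inf` outside the bounded regime.
#' @examples
#' analytic_length_constant(mt_params(), pr = 0.95, vr = 5)  # ~2.75 um
#' analytic_length_constant(mt_params(), pr = 0, vr = 5)     # Inf (unbounded)
#' @export
analytic_length_constant <- function(mt, pr, vr) {
  regime <- classify_growth_regime(mt, pr, vr)
  if (regime != "bounded") return(Inf)
  v_g <- mt$v_plus - pr * vr
  if (v_g <= 0) return(0)
  v_s <- mt$v_minus + pr * vr
  1 / (mt$f_cat / v_g - mt$f_res / v_s)
}

# Semi-discrete right-hand side pieces for the advection-reaction system on
# a cell-centered grid. Growing density advects toward R at signed speed
# v_g (first-order upwind); shrinking density advects toward 0 at speed
# v_s > 0. Closed boundaries: growing flux out at R becomes shrinking
# density there (forced catastrophe); shrinking flux out at 0 becomes
# growing density (regrowth from the central domain); a growing phase with
# v_g < 0 simply accumulates against r = 0. Total mass is conserved by
# construction.
mf_step <- function(u, w, vg, vs, h, f_cat, f_res, dt) {
  n <- length(u)
  du <- -f_cat * u + f_res * w
  dw <- f_cat * u - f_res * w
  if (vg > 0) {
    flux <- vg * u
    du <- du + (c(0, flux[-n]) - flux) / h
    dw[n] <- dw[n] + flux[n] / h
  } else if (vg < 0) {
    s <- -vg
    outflow <- s * u
    outflow[1L] <- 0
    du <- du + (c(s * u[-1L], 0) - outflow) / h
  }
  fw <- vs * w
  dw <- dw + (c(fw[-1L], 0) - fw) / h
  du[1L] <- du[1L] + fw[1L] / h
  list(u = u + dt * du, w = w + dt * dw)
}

mf_speeds <- function(mt, pr, vr) {
  list(vg = mt$v_plus - pr * vr, vs = mt$v_minus + pr * vr)
}

mf_lead_fraction <- function(u, w, centers, h, cutoff_r) {
  tot <- sum(u + w) * h
  if (tot <= 0) return(0)
  sum((u + w)[centers > cutoff_r]) * h / tot
}

new_density_profile <- function(r, u, w, h) {
  structure(data.frame(r = r, p_plus = u, p_minus = w),
            h = h, class = c("density_profile", "data.frame"))
}

#' Transient solution of the mean-field tip-density equations
#'
#' Integrates the advection-reaction equations for the growing and
#' shrinking tip densities at fixed coupling `pr` and flow `vr`
#' (first-order upwind advection, explicit reaction exchange) with the same
#' boundary rules as the agent simulation: growing flux at `R` converts to
#' shrinking density (forced catastrophe) and shrinking flux at 0 converts
#' to growing density.  Total mass is conserved by construction.
#'
#' @param mt [mt_params()].
#' @param pr coupling probability.
#' @param vr retrograde flow speed, um/min.
#' @param geom [geometry()].
#' @param n_grid number of radial cells.
#' @param t_end integration time, min.
#' @param dt time step, min; defaults to 90% of the CFL limit
#'   `h / max(|v_g|, v_s)` (also capped so `dt * max(f_cat, f_res) <= 0.05`).
#'   Supplying a `dt` violating the CFL condition is an error.
#' @param record_stride steps between recorded leading-edge fractions.
#' @param init `"origin"` puts all (unit) mass in the first cell as growing
#'   density, matching [init_ensemble()]; `"uniform"` spreads it evenly
#'   across both phases; alternatively a list with numeric vectors `u` and
#'   `w` of length `n_grid` gives the initial densities directly.
#'
#' @return An object of class `mf_transient`: list with recorded `t`,
#'   `lead_frac` (leading-edge mass fraction over time), `density` (final
#'   [data.frame] of class `density_profile` with `r`, `p_plus`, `p_minus`),
#'   `mass` (total mass over time), and the discretisation used.
#' @examples
#' tr <- pde_transient(mt_params(), pr = 0.95, vr = 5, geometry(),
#'                     n_grid = 100, t_end = 5)
#' tail(tr$lead_frac, 1)
#' @export
pde_transient <- function(mt, pr, vr, geom, n_grid = 400, t_end = 50,
                          dt = NULL, record_stride = 10L,
                          init = c("origin", "uniform")) {
  if (!is.list(init)) init <- match.arg(init)
  stop_on_violations(check_mt_params(mt))
  n <- as.integer(n_grid)
  h <- geom$R / n
  centers <- (seq_len(n) - 0.5) * h
  sp <- mf_speeds(mt, pr, vr)
  vmax <- max(abs(sp$vg), sp$vs)
  if (is.null(dt)) dt <- min(0.9 * h / vmax, 0.05 / max(mt$f_cat, mt$f_res))
  if (vmax * dt > h)
    stop(sprintf("CFL violation: dt = %g exceeds h / max speed = %g", dt, h / vmax),
         call. = FALSE)
  u <- numeric(n); w <- numeric(n)
  if (is.list(init)) {
    stopifnot(length(init$u) == n, length(init$w) == n)
    u <- as.numeric(init$u); w <- as.numeric(init$w)
  } else if (init == "origin") u[1L] <- 1 / h
  else { u[] <- 0.5 / geom$R; w[] <- 0.5 / geom$R }
  cutoff_r <- geom$leading_edge_cutoff * geom$R

  n_steps <- ceiling(t_end / dt)
  n_rec <- n_steps %/% record_stride + 1L
  t_rec <- lf_rec <- mass_rec <- numeric(n_rec)
  k <- 1L
  t_rec[k] <- 0
  lf_rec[k] <- mf_lead_fraction(u, w, centers, h, cutoff_r)
  mass_rec[k] <- sum(u + w) * h
  for (s in seq_len(n_steps)) {
    st <- mf_step(u, w, sp$vg, sp$vs, h, mt$f_cat, mt$f_res, dt)
    u <- st$u; w <- st$w
    if (s %% record_stride == 0L) {
      k <- k + 1L
      t_rec[k] <- s * dt
      lf_rec[k] <- mf_lead_fraction(u, w, centers, h, cutoff_r)
      mass_rec[k] <- sum(u + w) * h
    }
  }
  structure(list(t = t_rec[seq_len(k)], lead_frac = lf_rec[seq_len(k)],
                 mass = mass_rec[seq_len(k)],
                 density = new_density_profile(centers, u, w, h),
                 n_grid = n, h = h, dt = dt, pr = pr, vr = vr),
            class = "mf_transient")
}

# Sparse generator matrix of the semi-discrete system, state x = c(u, w).
# Duplicate (i, j) triplets are summed by Matrix::sparseMatrix.
mf_generator <- function(mt, pr, vr, n, h) {
  sp <- mf_speeds(mt, pr, vr)
  iu <- seq_len(n); iw <- n + iu
  ti <- c(iu, iu, iw, iw)                       # reaction exchange
  tj <- c(iu, iw, iu, iw)
  tx <- c(rep(-mt$f_cat, n), rep(mt$f_res, n),
          rep(mt$f_cat, n), rep(-mt$f_res, n))
  # growing-phase advection
  if (sp$vg > 0) {
    a <- sp$vg / h
    ti <- c(ti, iu, iu[-1L], 2L * n)            # forced catastrophe at R
    tj <- c(tj, iu, iu[-n], n)
    tx <- c(tx, rep(-a, n), rep(a, n - 1L), a)
  } else if (sp$vg < 0) {
    a <- -sp$vg / h
    ti <- c(ti, iu[-1L], iu[-n])
    tj <- c(tj, iu[-1L], iu[-1L])
    tx <- c(tx, rep(-a, n - 1L), rep(a, n - 1L))
  }
  # shrinking-phase advection (toward 0)
  a <- sp$vs / h
  ti <- c(ti, iw, iw[-n], 1L)                   # regrowth at r = 0
  tj <- c(tj, iw, iw[-1L], n + 1L)
  tx <- c(tx, rep(-a, n), rep(a, n - 1L), a)
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(2L * n, 2L * n))
}

#' Steady state of the mean-field tip-density equations
#'
#' Either solves the steady linear system of the semi-discrete equations
#' directly (null vector of the conservative generator, normalised to unit
#' mass) or time-integrates [pde_transient()] until the leading-edge mass
#' fraction stops changing.  The two paths agree to solver tolerance.
#'
#' @inheritParams pde_transient
#' @param method `"direct"` (linear solve) or `"integrate"`.
#' @param tol convergence tolerance on successive leading-edge fractions
#'   (integrate path).
#' @param max_time step budget for the integrate path, min of model time.
#' @return A `density_profile` data.frame (`r`, `p_plus`, `p_minus`, unit
#'   total mass) with attributes `lead_frac`, `h`, `method`.
#' @examples
#' ss <- pde_steady_state(mt_params(), pr = 0.95, vr = 5, geometry(),
#'                        n_grid = 100)
#' attr(ss, "lead_frac")
#' @export
pde_steady_state <- function(mt, pr, vr, geom, n_grid = 400,
                             method = c("direct", "integrate"),
                             tol = 1e-8, max_time = 5000) {
  method <- match.arg(method)
  n <- as.integer(n_grid)
  h <- geom$R / n
  centers <- (seq_len(n) - 0.5) * h
  cutoff_r <- geom$leading_edge_cutoff * geom$R
  if (method == "direct") {
    G <- mf_generator(mt, pr, vr, n, h)
    # columns of G sum to zero (mass conservation), so the rows are linearly
    # dependent: replace one with the unit-mass constraint.
    A <- G
    A[1L, ] <- h
    b <- c(1, numeric(2L * n - 1L))
    x <- as.numeric(Matrix::solve(A, b))
    x[x < 0 & x > -1e-10] <- 0
    u <- x[seq_len(n)]; w <- x[n + seq_len(n)]
  } else {
    sp <- mf_speeds(mt, pr, vr)
    vmax <- max(abs(sp$vg), sp$vs)
    dt <- min(0.9 * h / vmax, 0.05 / max(mt$f_cat, mt$f_res))
    u <- rep(0.5 / geom$R, n); w <- rep(0.5 / geom$R, n)
    chunk <- 200L
    lf_prev <- mf_lead_fraction(u, w, centers, h, cutoff_r)
    t_done <- 0
    converged <- FALSE
    while (t_done < max_time) {
      for (s in seq_len(chunk)) {
        st <- mf_step(u, w, sp$vg, sp$vs, h, mt$f_cat, mt$f_res, dt)
        u <- st$u; w <- st$w
      }
      t_done <- t_done + chunk * dt
      lf <- mf_lead_fraction(u, w, centers, h, cutoff_r)
      if (abs(lf - lf_prev) < tol) { converged <- TRUE; break }
      lf_prev <- lf
    }
    if (!converged)
      stop(sprintf("steady state not reached within %g min of model time (last change %.3g)",
                   max_time, abs(lf - lf_prev)), call. = FALSE)
  }
  out <- new_density_profile(centers, u, w, h)
  attr(out, "lead_frac") <- mf_lead_fraction(u, w, centers, h, cutoff_r)
  attr(out, "method") <- method
  out
}

#' Self-consistent mean-field fixed point of the MT-adhesion feedback
#'
#' Closes the positive-feedback loop deterministically: the steady-state
#' leading-edge mass fraction at flow speed `vr` is mapped through the force
#' balance `vr = v0 / (1 + beta * p)` and iterated (damped fixed-point
#' iteration `p <- (1 - omega) p + omega M(vr(p))`) until self-consistent.
#' Serves as the brute-force oracle for the stochastic simulation: the
#' agent-based steady-state `p_mean` should match `p_star` to sampling
#' error.
#'
#' @param params [gc_params()] bundle.
#' @param theta_deg angle in degrees determining the coupling probability.
#' @param omega damping factor in `(0, 1]`; damping guards against
#'   overshoot of the positive feedback at large `beta`.
#' @param tol convergence tolerance on successive `p` iterates.
#' @param max_iter iteration budget.
#' @param n_grid radial cells for the inner [pde_steady_state()] solves.
#' @return An object of class `fixed_point`: list with `p_star`, `vr_star`,
#'   `iterations`, `residual`, `theta_deg`, `pr`.
#' @examples
#' p <- gc_params(actin = actin_params(beta = 0.1),
#'                grad = gradient_params(A = 0.9))
#' self_consistent_fixed_point(p, 180, n_grid = 100)
#' @export
self_consistent_fixed_point <- function(params, theta_deg, omega = 0.5,
                                        tol = 1e-6, max_iter = 200,
                                        n_grid = 400) {
  pr <- coupling_probability(theta_deg, params$grad)
  actin <- params$actin
  M <- function(vr) attr(pde_steady_state(params$mt, pr, vr, params$geom,
                                          n_grid = n_grid, method = "direct"),
                         "lead_frac")
  if (actin$beta == 0) {
    p_star <- M(actin$v0)
    return(structure(list(p_star = p_star, vr_star = actin$v0,
                          iterations = 1L, residual = 0,
                          theta_deg = theta_deg, pr = pr),
                     class = "fixed_point"))
  }
  p <- M(actin$v0)   # start from the feedback-free solution
  for (k in seq_len(max_iter)) {
    vr <- retrograde_speed(p, actin)
    p_new <- (1 - omega) * p + omega * M(vr)
    if (abs(p_new - p) < tol) {
      vr_star <- retrograde_speed(p_new, actin)
      return(structure(list(p_star = p_new, vr_star = vr_star,
                            iterations = k, residual = abs(p_new - p),
                            theta_deg = theta_deg, pr = pr),
                       class = "fixed_point"))
    }
    p <- p_new
  }
  stop(sprintf("fixed point not converged in %d iterations; last bracket [%.6g, %.6g]",
               max_iter, min(p, p_new), max(p, p_new)), call. = FALSE)
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Mean-field fixed point at theta = %g deg (pr = %.3f)\n",
              x$theta_deg, x$pr))
  cat(sprintf("  p* = %.5f, vr* = %.4f um/min (%d iterations, residual %.2g)\n",
              x$p_star, x$vr_star, x$iterations, x$residual))
  invisible(x)
}
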