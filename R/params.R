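#' Microtubule dynamic-instability parameters
#'
#' Rates and speeds of the two-state (growing/shrinking) microtubule tip
#' model.  Defaults are estimates from fluorescent imaging of MTs in
#' *Aplysia* bag cell growth cones.
#'
#' @param f_cat catastrophe frequency (growing to shrinking), per minute.
#' @param f_res rescue frequency (shrinking to growing), per minute.
#' @param v_plus polymerization speed, um/min.
#' @param v_minus depolymerization speed, um/min.
#'
#' @return An object of class `mt_params`.
#' @seealso [actin_params()], [gradient_params()], [geometry()], [gc_params()]
#' @examples
#' mt_params()
#' @export
mt_params <- function(f_cat = 0.61, f_res = 1.79, v_plus = 6.0, v_minus = 9.6) {
  x <- structure(list(f_cat = f_cat, f_res = f_res,
                      v_plus = v_plus, v_minus = v_minus),
                 class = "mt_params")
  stop_on_violations(check_mt_params(x))
  x
}

#' Actin retrograde-flow and clutch parameters
#'
#' The force balance on the peripheral f-actin network gives a retrograde
#' flow speed `v_r = v0 / (1 + beta * p)`, where `p` is the fraction of MTs
#' at the leading edge: `v0` is the flow speed with no leading-edge MTs and
#' `beta` is the sensitivity of substrate adhesion to leading-edge MTs
#' (added viscous resistance per unit `p`, relative to the baseline
#' resistance).  Leading-edge protrusion is `v_cell = vp - v_r` (molecular
#' clutch).
#'
#' @param v0 maximum actin retrograde flow speed, um/min.
#' @param vp leading-edge actin polymerization speed, um/min.  The default
#'   equals `v0`, the "treadmilling" reference condition in which protrusion
#'   is zero without leading-edge MTs.
#' @param beta adhesion sensitivity to leading-edge MTs, dimensionless,
#'   `>= 0`.  `beta = 0` disables the MT-adhesion feedback.
#'
#' @return An object of class `actin_params`.
#' @examples
#' actin_params(beta = 0.1)
#' @export
actin_params <- function(v0 = 5, vp = 5, beta = 0) {
  x <- structure(list(v0 = v0, vp = vp, beta = beta), class = "actin_params")
  stop_on_violations(check_actin_params(x))
  x
}

#' Guidance-cue gradient parameters
#'
#' The MT-actin coupling probability varies with angular position as
#' `pr(theta) = pr0 * (1 - A * cos(theta))`: `pr0` is the coupling
#' probability at `theta = 90` degrees (orthogonal to the gradient) and `A`
#' is the dimensionless gradient steepness.  `A = 0` is a spatially uniform
#' cue; `A` near 1 gives maximal asymmetry in coupling across the growth
#' cone.  Validity requires `pr0 * (1 + A) <= 1` so the formula yields a
#' probability at every angle.
#'
#' @param pr0 coupling probability at `theta = 90` degrees, in `[0, 1]`.
#' @param A gradient steepness, dimensionless, in `[0, 1]`.
#'
#' @return An object of class `gradient_params`.
#' @examples
#' gradient_params(A = 0.9)
#' @export
gradient_params <- function(pr0 = 0.5, A = 0) {
  x <- structure(list(pr0 = pr0, A = A), class = "gradient_params")
  stop_on_violations(check_gradient_params(x))
  x
}

#' Growth cone geometry
#'
#' The growth cone is modelled as a semicircle of radius `R`; each angular
#' coordinate `theta` in `[0, 180]` degrees carries an independent 1-D
#' radial slice along which MT tips move.  The leading-edge zone is
#' `r > leading_edge_cutoff * R` (strict inequality).
#'
#' @param R growth cone radius, um.
#' @param leading_edge_cutoff fraction of `R` defining the leading-edge
#'   zone, in `(0, 1)`.
#' @param theta_grid strictly increasing angles in degrees, spanning
#'   `[0, 180]` (first element 0, last 180).
#'
#' @return An object of class `gc_geometry`.
#' @examples
#' geometry()
#' @export
geometry <- function(R = 10, leading_edge_cutoff = 0.75,
                     theta_grid = seq(0, 180, by = 10)) {
  x <- structure(list(R = R, leading_edge_cutoff = leading_edge_cutoff,
                      theta_grid = theta_grid),
                 class = "gc_geometry")
  stop_on_violations(check_geometry(x))
  x
}

is_num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)

check_mt_params <- function(x) {
  msgs <- character()
  for (f in c("f_cat", "f_res", "v_plus", "v_minus"))
    if (!is_num1(x[[f]]) || x[[f]] <= 0)
      msgs <- c(msgs, sprintf("mt.%s: must be a single finite number > 0", f))
  msgs
}

check_actin_params <- function(x) {
  msgs <- character()
  if (!is_num1(x$v0) || x$v0 <= 0)
    msgs <- c(msgs, "actin.v0: must be a single finite number > 0")
  if (!is_num1(x$vp) || x$vp < 0)
    msgs <- c(msgs, "actin.vp: must be a single finite number >= 0")
  if (!is_num1(x$beta) || x$beta < 0)
    msgs <- c(msgs, "actin.beta: must be a single finite number >= 0")
  msgs
}

check_gradient_params <- function(x) {
  msgs <- character()
  if (!is_num1(x$pr0) || x$pr0 < 0 || x$pr0 > 1)
    msgs <- c(msgs, "grad.pr0: must lie in [0, 1]")
  if (!is_num1(x$A) || x$A < 0 || x$A > 1)
    msgs <- c(msgs, "grad.A: must lie in [0, 1]")
  if (length(msgs) == 0L && x$pr0 * (1 + x$A) > 1)
    msgs <- c(msgs, sprintf(
      "grad: pr0 * (1 + A) = %.4g exceeds 1; coupling probability would leave [0, 1]",
      x$pr0 * (1 + x$A)))
  msgs
}

check_geometry <- function(x) {
  msgs <- character()
  if (!is_num1(x$R) || x$R <= 0)
    msgs <- c(msgs, "geom.R: must be a single finite number > 0")
  if (!is_num1(x$leading_edge_cutoff) ||
      x$leading_edge_cutoff <= 0 || x$leading_edge_cutoff >= 1)
    msgs <- c(msgs, "geom.leading_edge_cutoff: must lie strictly in (0, 1)")
  tg <- x$theta_grid
  if (!is.numeric(tg) || length(tg) < 2L || anyNA(tg))
    msgs <- c(msgs, "geom.theta_grid: must be a numeric vector of >= 2 angles")
  else {
    if (any(diff(tg) <= 0))
      msgs <- c(msgs, "geom.theta_grid: must be strictly increasing")
    if (tg[1L] != 0 || tg[length(tg)] != 180)
      msgs <- c(msgs, "geom.theta_grid: must start at 0 and end at 180 degrees")
  }
  msgs
}

stop_on_violations <- function(msgs) {
  if (length(msgs))
    stop("invalid parameters:\n", paste0("  - ", msgs, collapse = "\n"),
         call. = FALSE)
  invisible(NULL)
}

#' Validate a full parameter bundle
#'
#' Checks every invariant of the four parameter groups and aggregates all
#' violations into a single error naming each offending field.
#'
#' @param mt [mt_params()].
#' @param actin [actin_params()].
#' @param grad [gradient_params()].
#' @param geom [geometry()].
#'
#' @return Invisibly, a `gc_params` bundle (see [gc_params()]) if all
#'   invariants hold; otherwise an error listing every violation.
#' @examples
#' validate_params(mt_params(), actin_params(), gradient_params(), geometry())
#' @export
validate_params <- function(mt, actin, grad, geom) {
  msgs <- c(check_mt_params(mt), check_actin_params(actin),
            check_gradient_params(grad), check_geometry(geom))
  stop_on_violations(msgs)
  invisible(structure(list(mt = mt, actin = actin, grad = grad, geom = geom),
                      class = "gc_params"))
}

#' Bundle and validate model parameters
#'
#' Convenience constructor joining the four parameter groups into one
#' validated bundle, the object every simulation function takes.
#'
#' @inheritParams validate_params
#' @return An object of class `gc_params` with elements `mt`, `actin`,
#'   `grad`, `geom`.
#' @examples
#' p <- gc_params(actin = actin_params(beta = 0.1),
#'                grad = gradient_params(A = 0.9))
#' p
#' @export
gc_params <- function(mt = mt_params(), actin = actin_params(),
                      grad = gradient_params(), geom = geometry()) {
  out <- validate_params(mt, actin, grad, geom)
  out
}

#' @export
print.gc_params <- function(x, ...) {
  cat("Growth cone model parameters\n")
  cat(sprintf("  MT:    f_cat = %g /min, f_res = %g /min, v+ = %g, v- = %g um/min\n",
              x$mt$f_cat, x$mt$f_res, x$mt$v_plus, x$mt$v_minus))
  cat(sprintf("  actin: v0 = %g um/min, vp = %g um/min, beta = %g\n",
              x$actin$v0, x$actin$vp, x$actin$beta))
  cat(sprintf("  cue:   pr0 = %g, A = %g\n", x$grad$pr0, x$grad$A))
  cat(sprintf("  geom:  R = %g um, leading edge r > %g R, %d angles on [0, 180]\n",
              x$geom$R, x$geom$leading_edge_cutoff, length(x$geom$theta_grid)))
  invisible(x)
}

#' Simulation controls for the agent-based model
#'
#' @param dt time step, min.  Must satisfy `dt * max(f_cat, f_res) <= 0.05`
#'   (first-order switching probabilities) and
#'   `dt * (v_plus + v_minus + v0) <= 0.1 * R` (spatial resolution); both are
#'   enforced against the model parameters when a simulation starts.
#' @param t_total total simulated time, min.
#' @param burn_in initial time excluded from steady-state averages, min.
#' @param n_mt number of MT agents per angular coordinate.
#' @param seed master RNG seed; per-angle substreams are derived from it.
#' @param coupling_mode `"mean"` uses the deterministic effective tip drift
#'   `v_plus - pr * vr` / `v_minus + pr * vr`; `"bernoulli"` redraws the
#'   MT-actin coupling indicator per MT per step with probability `pr`.
#' @param record_stride number of steps between recorded samples.
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(t_total = 20, burn_in = 10)
#' @export
sim_config <- function(dt = 0.005, t_total = 100, burn_in = 50, n_mt = 1000,
                       seed = 1L, coupling_mode = c("mean", "bernoulli"),
                       record_stride = 20L) {
  coupling_mode <- match.arg(coupling_mode)
  x <- structure(list(dt = dt, t_total = t_total, burn_in = burn_in,
                      n_mt = as.integer(n_mt), seed = as.integer(seed),
                      coupling_mode = coupling_mode,
                      record_stride = as.integer(record_stride)),
                 class = "sim_config")
  stop_on_violations(check_sim_config(x))
  x
}

check_sim_config <- function(cfg, params = NULL) {
  msgs <- character()
  if (!is_num1(cfg$dt) || cfg$dt <= 0)
    msgs <- c(msgs, "sim.dt: must be a single finite number > 0")
  if (!is_num1(cfg$t_total) || cfg$t_total <= 0)
    msgs <- c(msgs, "sim.t_total: must be > 0")
  if (!is_num1(cfg$burn_in) || cfg$burn_in < 0 || cfg$burn_in >= cfg$t_total)
    msgs <- c(msgs, "sim.burn_in: must satisfy 0 <= burn_in < t_total")
  if (!is_num1(cfg$n_mt) || cfg$n_mt < 1)
    msgs <- c(msgs, "sim.n_mt: must be >= 1")
  if (!is_num1(cfg$record_stride) || cfg$record_stride < 1)
    msgs <- c(msgs, "sim.record_stride: must be >= 1")
  if (!is.character(cfg$coupling_mode) ||
      !cfg$coupling_mode %in% c("mean", "bernoulli"))
    msgs <- c(msgs, "sim.coupling_mode: must be \"mean\" or \"bernoulli\"")
  if (!is.null(params) && length(msgs) == 0L) {
    if (cfg$dt * max(params$mt$f_cat, params$mt$f_res) > 0.05)
      msgs <- c(msgs, "sim.dt: dt * max(f_cat, f_res) exceeds 0.05; reduce dt")
    if (cfg$dt * (params$mt$v_plus + params$mt$v_minus + params$actin$v0) >
        0.1 * params$geom$R)
      msgs <- c(msgs, "sim.dt: dt * (v_plus + v_minus + v0) exceeds 0.1 * R; reduce dt")
  }
  msgs
}
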