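#' MT-actin coupling probability along the guidance gradient
#'
#' The probability that a microtubule entering the peripheral domain is
#' mechanically coupled to actin retrograde flow, as a function of angular
#' position: `pr(theta) = pr0 * (1 - A * cos(theta))`.  `theta = 0` faces up
#' the cue gradient (least coupling), `theta = 180` faces down it.  The
#' probability depends only on `theta`, never on the radial coordinate.
#'
#' @param theta_deg angle(s) in degrees, each in `[0, 180]`.
#' @param grad [gradient_params()].
#'
#' @return Coupling probability in `[0, 1]`, same length as `theta_deg`.
#' @examples
#' g <- gradient_params(pr0 = 0.5, A = 0.9)
#' coupling_probability(c(0, 90, 180), g)   # 0.05, 0.50, 0.95
#' @export
coupling_probability <- function(theta_deg, grad) {
  stop_on_violations(check_gradient_params(grad))
  if (!is.numeric(theta_deg) || anyNA(theta_deg) ||
      any(theta_deg < 0 | theta_deg > 180))
    stop("theta_deg must be numeric in [0, 180]", call. = FALSE)
  grad$pr0 * (1 - grad$A * cospi(theta_deg / 180))
}

#' Actin retrograde flow speed under leading-edge MT feedback
#'
#' Force balance on the peripheral f-actin network: leading-edge MTs add
#' viscous resistance (adhesion engagement), attenuating retrograde flow as
#' `vr = v0 / (1 + beta * p)`.
#'
#' @param p fraction of MTs past the leading-edge line, in `[0, 1]`
#'   (vectorized).
#' @param actin [actin_params()].
#'
#' @return Retrograde flow speed, um/min, in `[v0 / (1 + beta), v0]`.
#' @examples
#' retrograde_speed(c(0, 0.5, 1), actin_params(v0 = 5, beta = 1))
#' @export
retrograde_speed <- function(p, actin) {
  stop_on_violations(check_actin_params(actin))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p must be numeric in [0, 1]", call. = FALSE)
  actin$v0 / (1 + actin$beta * p)
}

#' Leading-edge protrusion speed (molecular clutch)
#'
#' Protrusion is the excess of leading-edge actin polymerization over
#' retrograde flow: `v_cell = vp - vr`.  Under the treadmilling reference
#' condition `vp = v0` it is non-negative, and combining with
#' [retrograde_speed()] gives the saturating clutch relation
#' `v_cell / v0 = beta * p / (1 + beta * p)`.
#'
#' @param vr retrograde flow speed, um/min, `>= 0` (vectorized).
#' @param actin [actin_params()].
#'
#' @return Protrusion speed, um/min (may be negative if `vp < vr`).
#' @examples
#' protrusion_speed(2.5, actin_params(v0 = 5, vp = 5))
#' @export
protrusion_speed <- function(vr, actin) {
  stop_on_violations(check_actin_params(actin))
  if (!is.numeric(vr) || anyNA(vr) || any(vr < 0))
    stop("vr must be numeric and >= 0", call. = FALSE)
  actin$vp - vr
}

#' Classify the MT growth regime at given coupling and flow
#'
#' With coupling probability `pr` and retrograde flow `vr`, tips grow at the
#' effective speed `v_g = v_plus - pr * vr` and shrink at
#' `v_s = v_minus + pr * vr`.  The two-state tip model is in *unbounded*
#' growth (persistent elongation, tips pile up at the leading edge) when
#' `v_g * f_res - v_s * f_cat > 0`, and *bounded* growth (finite
#' exponentially-distributed excursions) when it is negative.  The knife-edge
#' case is reported as `"marginal"`.  If `v_g <= 0` the mean tip drift is
#' retrograde in both phases and the regime is `"bounded"`.
#'
#' @param mt [mt_params()].
#' @param pr coupling probability in `[0, 1]`.
#' @param vr retrograde flow speed, um/min, `>= 0`.
#'
#' @return One of `"unbounded"`, `"bounded"`, `"marginal"`.
#' @examples
#' classify_growth_regime(mt_params(), pr = 0.05, vr = 5)  # "unbounded"
#' classify_growth_regime(mt_params(), pr = 0.95, vr = 5)  # "bounded"
#' @export
classify_growth_regime <- function(mt, pr, vr) {
  stop_on_violations(check_mt_params(mt))
  if (!is_num1(pr) || pr < 0 || pr > 1) stop("pr must lie in [0, 1]", call. = FALSE)
  if (!is_num1(vr) || vr < 0) stop("vr must be >= 0", call. = FALSE)
  v_g <- mt$v_plus - pr * vr
  v_s <- mt$v_minus + pr * vr
  if (v_s <= 0) stop("effective shrink speed v_minus + pr * vr must be > 0",
                     call. = FALSE)
  if (v_g <= 0) return("bounded")
  crit <- v_g * mt$f_res - v_s * mt$f_cat
  if (crit > 0) "unbounded" else if (crit < 0) "bounded" else "marginal"
}
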