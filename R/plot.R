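#' Plot a steady-state growth cone profile
#'
#' Three-panel base-graphics view of the angular profiles: leading-edge MT
#' fraction, actin retrograde flow speed, and local protrusion speed, with
#' the net protrusion angle in the title.
#'
#' @param x a `gc_profile` from [simulate_growth_cone()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.gc_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  tp <- attr(x, "theta_p")
  graphics::plot(x$theta_deg, x$p_mean, type = "b", pch = 19,
                 xlab = expression(theta ~ "(deg)"),
                 ylab = "leading-edge MT fraction p",
                 main = sprintf("theta_p = %s",
                                if (is.na(tp)) "undefined" else sprintf("%.1f deg", tp)))
  graphics::plot(x$theta_deg, x$vr_mean, type = "b", pch = 19,
                 xlab = expression(theta ~ "(deg)"),
                 ylab = "retrograde flow v_r (um/min)", main = "")
  graphics::plot(x$theta_deg, x$vcell_mean, type = "b", pch = 19,
                 xlab = expression(theta ~ "(deg)"),
                 ylab = "protrusion v_cell (um/min)", main = "")
  invisible(x)
}

#' Plot a per-angle time series
#'
#' @param x an `angle_series` from [simulate_angle()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.angle_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$p, type = "l",
                 xlab = "t (min)", ylab = "leading-edge MT fraction p",
                 main = sprintf("theta = %g deg", x$theta_deg))
  graphics::plot(x$t, x$vr, type = "l",
                 xlab = "t (min)", ylab = "v_r (um/min)", main = "")
  invisible(x)
}
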