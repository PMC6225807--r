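# Shared fixtures: parameter bundles built in code, and a reduced-scale
# simulation config for fast unit tests.

params_with <- function(A = 0, beta = 0, pr0 = 0.5, ...) {
  gc_params(mt = mt_params(),
            actin = actin_params(beta = beta),
            grad = gradient_params(pr0 = pr0, A = A),
            geom = geometry(...))
}

fast_cfg <- function(t_total = 10, burn_in = 5, n_mt = 100, seed = 1L,
                     record_stride = 10L, ...) {
  sim_config(t_total = t_total, burn_in = burn_in, n_mt = n_mt, seed = seed,
             record_stride = record_stride, ...)
}

# Hand-built ensemble at given positions (for boundary/fraction tests).
ensemble_at <- function(r, growing = rep(TRUE, length(r)), vr = 5,
                        theta_deg = 90) {
  structure(list(r = r, growing = growing, vr = vr,
                 theta_deg = theta_deg, t = 0),
            class = "ensemble_state")
}

# Hand-built recorded series (for summary tests).
series_of <- function(t, p, vr, params = params_with(), cfg = fast_cfg()) {
  structure(list(theta_deg = 90, pr = 0.5, t = t, p = p, vr = vr,
                 r = numeric(0), growing = logical(0), seed = 1L,
                 params = params, cfg = cfg),
            class = "angle_series")
}
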