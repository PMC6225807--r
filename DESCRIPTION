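Package: gcsteer
Title: Stochastic Microtubule-Actin Feedback Model of Growth Cone Turning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based stochastic simulation of growth cone steering by
    coordinated microtubule and actin dynamics. Microtubule tips undergo
    dynamic instability (catastrophe/rescue switching) with retrograde drift
    from transient coupling to actin retrograde flow; a guidance-cue gradient
    modulates the coupling probability across the growth cone, and
    accumulation of microtubules at the leading edge feeds back on
    adhesion-mediated attenuation of retrograde flow (molecular clutch).
    Provides the closed-form model relations, per-angle ensemble simulations,
    steady-state angular profiles and the net protrusion angle, a
    deterministic mean-field companion (two-state tip-density equations with
    drift, their steady states and a self-consistent fixed point) used as a
    verification oracle, parameter sweeps, and a configuration-driven
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
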