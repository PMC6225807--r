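# gcsteer

Stochastic simulation of growth cone turning driven by coordinated
microtubule (MT) and actin dynamics.

Growth cones — the motile tips of growing axons — steer by reorganizing
their cytoskeleton in response to gradients of guidance cues. `gcsteer`
implements a minimal mechanochemical model of that process for
computational cell biophysicists who want quantitative, testable
predictions of the MT distribution, actin retrograde flow, and protrusion
direction:

* MT tips undergo dynamic instability (catastrophe rate `f_c`, rescue rate
  `f_r`, speeds `v+`, `v-`) along radial slices of a semicircular growth
  cone, and are dragged rearward when coupled to actin retrograde flow, so
  effective tip speeds are `v_g = v+ − p_r v_r` and `v_s = v− + p_r v_r`.
* A cue gradient lowers the MT-actin coupling probability on the
  up-gradient side: `p_r(θ) = p_r0 (1 − A cos θ)`, with steepness
  `A ∈ [0, 1]`.
* Leading-edge MTs (tips past `0.75 R`, fraction `p`) engage the adhesion
  clutch, attenuating flow — `v_r = v0 / (1 + β p)` — and converting actin
  polymerization into protrusion, `v_cell = v_p − v_r`. Attenuated flow
  admits more MTs: a positive feedback with gain `β`.
* The net protrusion angle `θ_p` is the direction of the vector sum of the
  per-angle protrusion vectors; `θ_p = 0` means full alignment with the
  gradient, `θ_p = 90` means no turning.

The package provides the agent-based simulation (compiled inner loop,
fully seeded and reproducible), a deterministic mean-field companion (the
two-state tip-density equations with drift, their steady states, and a
self-consistent fixed point) used as a verification oracle, parameter
sweeps over `A` and `β`, and a configuration-driven CLI.

## Worked example

```r
library(gcsteer)

params <- gc_params(actin = actin_params(beta = 0.1),
                    grad  = gradient_params(pr0 = 0.5, A = 0.9))
cfg <- sim_config(seed = 1)        # 1000 MTs/angle, 100 min, 50 min burn-in
prof <- simulate_growth_cone(params, cfg)
prof
#> Growth cone steady-state profile (19 angles)
#>   net protrusion angle theta_p = 60.84 deg
#>  theta_deg      pr  p_mean     p_se vr_mean     vr_se vcell_mean  vcell_se ...
#>          0 0.05000 0.32422 0.001505   4.843 0.0007061    0.15701 0.0007061
#>         90 0.50000 0.22804 0.001645   4.889 0.0007866    0.11147 0.0007866
#>        180 0.95000 0.04254 0.001006   4.979 0.0004984    0.02118 0.0004984
```

Up the gradient (θ = 0) only 5% of MTs couple to actin flow: MTs are in
unbounded growth, a third of them sit past the leading-edge line, and flow
slows from 5 to 4.84 um/min, giving local protrusion of 0.16 um/min. Down
the gradient (θ = 180) 95% couple: bounded growth, 4% at the leading edge,
and near-treadmilling flow. The vector sum of the protrusion profile points
60.8 degrees from the gradient axis — the growth cone turns toward the cue.
Cross-check a single angle against the mean-field oracle:

```r
self_consistent_fixed_point(params, theta_deg = 180)
#> Mean-field fixed point at theta = 180 deg (pr = 0.950)
#>   p* = 0.04287, vr* = 4.9787 um/min (12 iterations, residual 7.7e-07)
```

Sweeps reproduce the model's central prediction — turning is strongest at
*intermediate* adhesion sensitivity, since a too-eager clutch engages on
both sides of the growth cone:

```r
sweep_protrusion(params, cfg, beta_values = c(0.01, 0.1, 1, 10))
```

## Command line

```sh
inst/scripts/gcsteer run cone --config cfg.yaml --seed 1 --out results/
inst/scripts/gcsteer validate --config cfg.yaml
```

Experiments: `angle` (time series per angle), `cone` (angular profile and
`θ_p`), `sweep-beta`, `sweep-A`, `meanfield-check` (agent vs. oracle).
Configs are flat YAML/JSON mappings over `default_config()`; outputs are
tidy CSVs plus a JSON provenance sidecar and a hash manifest.

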