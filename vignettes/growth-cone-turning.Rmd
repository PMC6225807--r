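---
title: "Modeling microtubule-actin feedback in growth cone turning"
author: "gcsteer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microtubule-actin feedback in growth cone turning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsteer)
```

## The model

A growth cone is idealized as a two-dimensional semicircle of radius $R$.
Each angular coordinate $\theta \in [0^\circ, 180^\circ]$ carries an
independent one-dimensional radial slice along which microtubule (MT) tips
move, $r \in [0, R]$, with $r = 0$ at the central (C) domain and $r = R$ at
the leading-edge membrane. $\theta = 0$ faces up the guidance-cue gradient,
$\theta = 90$ is the original growth axis.

Three coupled ingredients drive the dynamics:

**MT dynamic instability with retrograde drift.** Tips switch stochastically
between growing and shrinking phases with catastrophe frequency $f_c$ and
rescue frequency $f_r$. A tip that is mechanically coupled to the f-actin
network is dragged rearward at the actin retrograde flow speed $v_r$, so the
effective tip speeds are

$$v_g = v_+ - p_r v_r, \qquad v_s = v_- + p_r v_r,$$

where $p_r$ is the MT-actin coupling probability. In density form the
growing/shrinking tip densities $\rho_\pm(r, t)$ obey a two-state
advection-reaction system (the classical two-state tip model with an added
drift term); this continuum companion is implemented in
`pde_transient()` / `pde_steady_state()` and used as a verification oracle
for the stochastic simulation. The sign of $v_g f_r - v_s f_c$ separates
*unbounded* growth (tips reach the leading edge and persist there) from
*bounded* growth (excursion lengths exponentially distributed with constant
$\lambda = 1 / (f_c / v_g - f_r / v_s)$); `classify_growth_regime()` reports
the knife-edge case as `"marginal"` rather than silently binning it, so the
boundary itself is testable.

**Angular coupling gradient.** An attractive cue rising linearly across the
growth cone lowers MT-actin coupling on the up-gradient side:

$$p_r(\theta) = p_{r0}\,(1 - A \cos\theta),$$

with $p_{r0}$ the coupling probability at $\theta = 90$ and
$A \in [0, 1]$ the dimensionless gradient steepness. Validity requires
$p_{r0}(1 + A) \le 1$, enforced at construction. The coupling depends only
on $\theta$, never on $r$. We implement the linear form as written; no
saturation is applied for steep gradients, since the validity constraint
already keeps the formula inside $[0, 1]$.

**Molecular clutch with MT feedback.** The fraction $p$ of MTs whose tips
lie beyond the leading-edge line ($r > 0.75 R$, strict inequality) promotes
substrate adhesion, adding viscous resistance against retrograde flow:

$$\frac{v_r}{v_0} = \frac{1}{1 + \beta p}, \qquad v_{cell} = v_p - v_r,$$

where $v_0$ is the flow speed without leading-edge MTs, $\beta$ the
adhesion sensitivity, and $v_p$ the leading-edge actin polymerization
speed. Under the treadmilling reference condition $v_p = v_0$ these combine
into the saturating clutch relation
$v_{cell}/v_0 = \beta p / (1 + \beta p)$. Because attenuated flow lets still
more MTs reach the leading edge, the loop is a positive feedback.

The net protrusion direction $\theta_p$ is the polar angle of the vector sum
of the per-angle protrusion vectors $(v_{cell}\cos\theta,
v_{cell}\sin\theta)$, with equal angular weights. When the summed vector is
numerically zero (magnitude below $10^{-9} v_0 n_{angles}$, e.g. at
$\beta = 0$ under treadmilling) the direction is undefined and reported as
`NA` rather than an arbitrary angle.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `f_cat` | catastrophe frequency | 0.61 | min^-1 |
| `f_res` | rescue frequency | 1.79 | min^-1 |
| `v_plus` | MT polymerization speed | 6.0 | um/min |
| `v_minus` | MT depolymerization speed | 9.6 | um/min |
| `v0` | maximum retrograde flow speed | 5 | um/min |
| `vp` | actin polymerization speed | 5 | um/min |
| `beta` | adhesion sensitivity to leading-edge MTs | 0 | - |
| `pr0` | coupling probability at 90 degrees | 0.5 | - |
| `A` | gradient steepness | 0 | - |
| `R` | growth cone radius | 10 | um |

The rates and speeds are experimental estimates from fluorescent imaging of
*Aplysia* bag cell growth cones; `pr0 = 0.5` is a reference value of the
order of measured MT-flow coupling frequencies. `A` and `beta` are the two
free parameters the package exists to explore. The radius is never stated
by the experimental estimates; we default to $R = 10$ um, a typical large
growth cone scale. $R$ only sets absolute excursion lengths — the
dimensionless gradient response is governed by $A$ — so this choice does
not affect any angular or dimensionless result.

## The stochastic simulation

`simulate_angle()` evolves $N$ independent MT agents per angle with a fixed
time step `dt` (default 0.005 min):

1. each MT switches phase with first-order probabilities $f_c\,dt$ /
   $f_r\,dt$ (the constructor-enforced cap $f\,dt \le 0.05$ keeps the
   first-order error below about half a percent);
2. the tip moves by $\pm(v_\pm \mp c\,v_r)\,dt$, where the coupling
   indicator $c$ is either the probability $p_r$ itself (`coupling_mode =
   "mean"`, the default — the literal effective-drift reading of the tip
   equations) or a fresh Bernoulli($p_r$) draw per MT per step
   (`"bernoulli"`, agent-level realism). The two modes have identical mean
   drift and statistically indistinguishable steady states, which the test
   suite checks; we default to `"mean"` because it adds no extra variance
   beyond phase switching.
3. boundary rules: a tip reaching $R$ is clamped and forced into
   catastrophe (the membrane is a physical barrier); a shrinking tip
   reaching $0$ is clamped and switched to growing, modeling continual
   regrowth from the C domain and conserving the MT count. A growing tip
   whose drift is retrograde ($v_g < 0$) simply rests against $r = 0$.
4. $p$ is recomputed and $v_r$ updated instantaneously from the force
   balance. The force balance is algebraic, so no adhesion relaxation
   kinetics are introduced; `vr` at every recorded sample equals the force
   balance evaluated at that sample's $p$ bit-for-bit.

All MTs start at $r = 0$ growing, with $v_r = v_0$. Ties at exactly
$0.75R$ are a measure-zero event and are not counted as leading-edge
(strict inequality); the choice is arbitrary and immaterial.

The inner loop runs in compiled code using R's RNG stream; a pure-R
reference stepper (`step_ensemble()`) implements the identical scheme and
the test suite asserts the two are bit-identical under a shared seed.
Per-angle RNG substreams are derived deterministically from the master seed
and the angle value, so per-angle results are independent of grid order and
of one another, and a single angle can be reproduced in isolation.

`steady_state_summary()` averages the recorded samples with $t >$
`burn_in` (defaults: 100 min total, 50 min burn-in, samples every 0.1 min,
so 500 samples enter the average). Standard errors use
Flyvbjerg-Petersen blocking (repeated adjacent-pair averaging, taking the
largest SE across levels with at least 16 blocks), since successive samples
of $p$ are strongly autocorrelated on the MT turnover timescale
($\sim 1/f_c$).

## The mean-field oracle

The continuum system is discretized with first-order upwind advection on a
cell-centered grid (default $\Delta r = R/400$), chosen for positivity
preservation; boundary fluxes are converted between phases exactly as in
the agent rules, so total mass is conserved by construction (verified to
$10^{-6}$ in tests). The steady state is obtained either by time
integration to a $10^{-8}$ stopping tolerance or by a direct sparse linear
solve of the conservative generator with a unit-mass constraint row; the
two paths agree to $10^{-6}$ and the direct path is used inside the fixed
point. Upwind differencing is first-order, so steady-state leading-edge
fractions carry an $O(\Delta r)$ bias; grid-refinement tests bound it below
1% at the default grid, and where the test suite compares the oracle
against the stochastic simulation at tight sampling error it removes the
leading-order bias by Richardson extrapolation across two grids (and runs
the agents at a halved `dt` for the matching reason on the time axis).

`self_consistent_fixed_point()` closes the feedback loop deterministically
by damped iteration $p \leftarrow (1-\omega)p + \omega M(v_r(p))$, where
$M$ maps a flow speed to the steady-state leading-edge mass fraction. The
damping $\omega = 0.5$ guards against overshoot of the positive feedback at
large $\beta$; with $\beta = 0$ the loop is open and the fixed point is the
single open-loop solve. The test suite requires the stochastic steady state
to agree with the fixed point within three standard errors at five
parameter points spanning both growth regimes — this cross-validation is
the module's central purpose.

## What the simulation does and does not emulate

The generator reproduces the study conditions: Table-defaults rates and
speeds, 1000 MTs per angle, 19 angles at 10-degree spacing, and steady-state
averaging after burn-in. It emulates ensemble MT dynamics, the angular
coupling gradient, and the adhesion feedback. It does **not** emulate MT
bending or mechanics, filopodia, explicit actin filaments, molecular motors,
adhesion signaling kinetics, two-dimensional tip trajectories (the model is
a family of independent radial slices), or any coupling between neighboring
angular slices. Passing tests therefore validate the mathematical model and
its implementation, not the biology: real growth cones have finite MT
numbers per sector far below 1000, angular transport, and noisy gradients.

## Numerical and design choices

* Angles are degrees at every interface; speeds um/min; times minutes.
* `dt = 0.005` min keeps both the switching-probability error and the
  per-step displacement (at most about 0.1 um) small; constructors reject
  configurations violating either cap.
* Burn-in of half the run is conservative: relaxation times are minutes
  (set by $1/f_c$ and $R/v_g$), well under 50 min.
* The marginal growth regime returns its own label; the degenerate bounded
  case $v_g \le 0$ returns a zero length constant rather than a negative
  number from the exponential formula.
* Sweeps derive one reproducible seed per grid point from the master seed;
  a single-point sweep is bit-identical to a direct run.
* Tables are CSV, provenance JSON, and every output file is hashed into a
  manifest, so (config, seed) reproduces output hashes exactly.

Problem sizes used by the test suite: unit tests run reduced ensembles
(tens of MTs, a few minutes of model time); the end-to-end checks run the
full study conditions — five replicate 19-angle growth cones for the
uniform-cue symmetry check, six replicates per point for the five-point
oracle comparison, and 1500 agents for the length-distribution test —
sizes at which the standard errors are small enough to make the 3-SE
comparisons meaningful.

## Worked example

```{r example, eval = FALSE}
params <- gc_params(actin = actin_params(beta = 0.1),
                    grad = gradient_params(pr0 = 0.5, A = 0.9))
cfg <- sim_config(seed = 1)
prof <- simulate_growth_cone(params, cfg)
prof                      # per-angle steady state
attr(prof, "theta_p")     # net protrusion angle, degrees

fp <- self_consistent_fixed_point(params, theta_deg = 180)
fp$p_star                 # mean-field leading-edge fraction at 180 degrees
```

## Known limitations

* The first-order agent scheme and upwind PDE each carry small
  discretization biases (sub-percent at defaults); exact agreement between
  them is only expected after extrapolation, as described above.
* The fixed-point iteration can fail to converge for extreme $\beta$ if
  the feedback map is steeper than the damping accommodates; the error
  reports the last bracket, and lowering `omega` resolves it.
* Blocked standard errors are estimates; with strongly autocorrelated
  series and short runs they can undershoot, which is why the end-to-end
  comparisons prefer replicate-based errors.
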