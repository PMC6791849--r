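---
title: "Modelling cell-envelope resealing after pulsed electric fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell-envelope resealing after pulsed electric fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pefreseal)
```

## The physical picture

A microsecond pulsed electric field (PEF) opens transient, non-equilibrium
pores in both layers of the yeast cell envelope. Each layer reseals on its
own clock, and each clock is read through a different probe:

* **Cell wall** — the lipophilic cation TPP⁺ crosses the wall through its
  pores; an ion-selective electrode follows its disappearance from the
  supernatant. The wall is the rate-limiting barrier: wall-free
  spheroplasts show no field dependence of uptake at all, which in this
  model is exactly the `A = 0` special case.
* **Plasma membrane** — a membrane-impermeant nucleic-acid dye only stains
  cells whose membrane is still porous, so fluorescence intensity versus
  the dye-addition delay reads out membrane resealing.

## The uptake model and its assumptions

Absorption of TPP⁺ during the slow stage follows a pseudo-second-order law,

$$\frac{dN}{dt} = k_a(t)\,(N_m - N)(N_s - N), \qquad N(0) = 0,$$

with `N` the absorbed amount (µM), `N_m` its saturation value and `N_s` the
available pool at the start of the slow stage. The model's assumptions are
that (a) permeation is proportional to the number of wall pores, (b) the
pulse creates an excess of pores that decays by a first-order law with
lifetime `τ_d`, and (c) equilibrium pores provide the time-independent
baseline `k_a0`. Hence

$$k_a(t) = k_{a0} + A\,e^{-\Delta t/\tau_d}\,e^{-t/\tau_d},$$

where `Δt` is the delay between the pulse and TPP⁺ addition (pores decay
unobserved during `Δt`) and `A` is the pore-term amplitude at `Δt = 0`.
`A` is the *identifiable product* of the pore-count constant and the
initial pore excess; the two factors never appear separately in any
observable, so the package parameterizes only their product.

Since `k_a` depends on time only, separation of variables gives the closed
form

$$\frac{N}{N_m} = \frac{1 - S_{\Delta t}}{1 - R\,S_{\Delta t}},\quad
R = \frac{N_m}{N_s},\quad
S_{\Delta t} = e^{(N_m - N_s)\,K(t)},$$

with the accumulated rate integral
$K(t) = k_{a0} t + A \tau_d e^{-\Delta t/\tau_d}(1 - e^{-t/\tau_d})$.
The untreated baseline (`A = 0`) is the dashed-line level
$N_0/N_m = (1 - S_0)/(1 - R\,S_0)$, $S_0 = e^{(N_m-N_s)k_{a0}t}$.

Above a threshold field `E_th,p` the amplitude scales with pulse parameters
as

$$A = b\,(E_p - E_{th,p})^2 f^2 \left[1 - e^{-t_p/t_{ch}}\right]^2 ,$$

with `f` the cell shape factor (1.5 for spheres) and `t_ch` the membrane
charging time. The charging bracket is written with the *negative*
exponent: that is the physically saturating form — a pulse much longer than
the charging time cannot keep increasing the pore yield — and the package
uses it consistently.

The membrane readout is a plain exponential decay to a residual,
$I(\Delta t) = I_0 e^{-\Delta t/\tau_l} + I_r$, with `τ_l` the lipidic-pore
lifetime. The residual `I_r` absorbs slower, extended resealing (the
experiments keep cells on ice); the package does not model that tail beyond
the offset.

## Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `N_s` | TPP⁺ pool at start of slow stage | µM | 1.0 (the initial probe concentration) |
| `N_m` | saturation uptake | µM | 0.5 (only `R = N_m/N_s` matters; free choice, documented) |
| `t` | incubation time | s | 180 (the 3-min design) |
| `k_a0` | baseline absorption coefficient | 1/(µM s) | calibrated, 7.33e-4 |
| `A` | pore-term amplitude | 1/(µM s) | calibrated, 0.0493 at 5.85 kV/cm |
| `τ_d` | wall-pore lifetime | s | 24 |
| `τ_l` | membrane-pore lifetime | s | 20 |
| `E_th,p` | threshold field | kV/cm | 2.0 |
| `t_ch` | membrane charging time | µs | 1 (illustrative; at 150 µs pulses the bracket is ≈ 1 and cancels from field-to-field ratios) |
| `f` | shape factor | — | 1.5 |

Time is seconds internally; pulse durations and charging times are
microseconds (their ratio is dimensionless); fields are kV/cm;
concentrations µM.

## Calibration from anchors

Raw uptake measurements are not redistributable, but two dimensionless
anchors pin the model down: the untreated 3-minute level
`N0/N_m = 0.12` and the zero-delay level `N/N_m = 0.65` at the reference
field 5.85 kV/cm. Both inversions are algebraic:

```{r calibrate}
constants <- uptake_constants(N_m = 0.5, N_s = 1.0)
cal <- calibrate_from_anchors(anchor_set(0.12, 0.65, 180, tau_d = 24),
                              constants)
c(k_a0 = cal$k_a0, A_reference = cal$A_reference)
baseline_uptake(constants, cal$k_a0, 180)            # reproduces 0.12
uptake_with_delay(constants, cal$wall, 180, 0)       # reproduces 0.65
```

The forward model reproduces both anchors to machine precision (the tests
require 1e-10). Amplitudes at the two lower fields are spread from the
reference through the field-response law with `E_th,p = 2.0` kV/cm; with a
common pulse duration the charging bracket cancels, so the scaling is just
`(E − E_th,p)²` relative to the reference field. These derived amplitudes
are a modelling choice, not a measured quantity, and are recorded in every
generator manifest.

## Fitting

Both fits are bounded Levenberg–Marquardt least squares (`minpack.lm`),
unweighted — the designs report one mean series per condition, with no
stated error model that would justify weights. Bounds keep the search in
the physical region: lifetimes in `[0.01, 1e4]` s, amplitudes and
intensities non-negative. Starting values are data-driven (log-linear tail
fit for the fluorescence decay; algebraic inversion of the first delay
point for the uptake amplitudes), so fits are deterministic given the data.

The multi-field uptake fit shares one `τ_d` across fields with one
amplitude per field — the scientific claim being tested is precisely that
the wall lifetime does not depend on field strength. `k_a0` is fixed at its
calibrated value by default because the untreated level is measured
separately in this design; `fix_k_a0 = FALSE` frees it. Weak-signal cases
are flagged rather than hidden: an amplitude within 2 standard errors of
zero marks the affected field, and if every field is that weak the result
carries `tau_d_unidentifiable` (a constant fluorescence series likewise
returns a flagged, non-converged result).

## Numerical choices

* **Equal roots.** When `|N_m − N_s| < 1e-9 N_s` the two-root closed form
  degenerates; the package switches continuously to the limit solution
  `N = N_m − N_m/(1 + N_m K)` of `dN/dt = k_a (N_m − N)²`.
* **Oracle.** `integrate_uptake_ode()` integrates the ODE with fixed-step
  classical RK4, step at most `0.01·min(τ_d, 1/(k_a,max N_s))`, so the
  oracle is bit-for-bit reproducible. Closed form and oracle agree to
  1e-6 relative over 100 randomized parameter sets in the test suite.
* **Ties and degenerate inputs.** Validation errors (negative times,
  non-monotone grids, ratios outside `[0, 1]`, `N_m > N_s`) carry the
  condition class `pef_validation_error`; the command-line wrapper maps
  them to exit code 2 and convergence failures to 3.

## What the synthetic data emulate — and what they do not

The generators reproduce the three designs' structure: the ten post-pulse
delays (5–180 s) at three fields with 180 s incubation for uptake, the six
dye delays (10–600 s) for fluorescence, and the three-stage electrode trace
(fast adsorption, delay plateau, slow absorption; the plateau is removed
when the suspension was pulsed). Noise is additive Gaussian on the reported
quantity, ratios clipped to `[0, 1]`. The published curves do not state a
noise magnitude; the defaults `σ_ratio = 0.03` and `σ_fluor = 2` a.u. are
assumptions chosen so that per-curve adjusted R² on synthetic uptake data
spans roughly the published 0.34–0.85 range, and they are stated as such.
Real electrode traces additionally carry drift and a Nernstian response
that the concentration-domain simulator does not model, and real replicate
noise need not be Gaussian or homoscedastic — passing recovery tests show
estimator correctness under the stated noise model, not robustness to
misspecification. Stage-I/II trace constants (`stage1_tau = 3` s,
`stage2_duration = 240` s) are illustrative, since the source experiments
describe those stages only qualitatively.

One master seed drives each generator call; replicate streams are drawn
sequentially from it, so a fixed seed reproduces every replicate exactly.

## Monte-Carlo recovery

```{r recover}
rec <- recovery_experiment(list(
  model = "fluorescence", params = fluorescence_params(100, 20, 20),
  noise = noise_spec(sigma = 2, seed = 20191014, n_replicates = 100)))
rec[, c("parameter", "true", "mean_estimate", "bias", "rmse", "coverage95")]
```

The packaged experiments use 100 replicates of the full designs (30 uptake
points, 6 fluorescence points per replicate), which a laptop completes in
well under a minute; both lifetimes are recovered with mean bias well
inside ±2 s of their generating values (24 s wall, 20 s membrane). The
six-point fluorescence design leaves `τ_l` slightly downward-biased at
σ = 2 a.u. — an expected small-sample nonlinearity effect, well within the
tolerance the recovery claims use.

## Known limitations

* `b`, `E_th,p` and `t_ch` are not separately identifiable from these
  designs; only per-field amplitudes are. The parametric field law is
  provided for scaling and simulation, with its constants documented as
  defaults rather than estimates.
* The equilibrium pore amount has no independent representation; it is
  absorbed into the definition of the baseline and the pore excess.
* Stage I adsorption and the stage II delay enter only through `N_s` and
  the trace simulator, not the closed-form uptake model.
* No Bayesian inference or bootstrap intervals; standard errors are Wald
  errors from the least-squares covariance.
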