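# pefreseal

Kinetics of yeast cell-envelope resealing after pulsed-electric-field (PEF)
treatment.

Microsecond high-voltage pulses transiently permeabilize the *Saccharomyces
cerevisiae* cell envelope. The wall's recovery is observed through the uptake
of the lipophilic cation TPP⁺ (tetraphenylphosphonium, followed with an
ion-selective electrode), and the plasma membrane's recovery through the
fluorescence of a membrane-impermeant dye added at increasing delays after
the pulse. `pefreseal` implements the kinetic models behind both readouts,
calibrates them from printed anchor ratios, fits the pore lifetimes by
bounded nonlinear least squares, and generates synthetic datasets with the
statistical structure of the three experimental designs — so the whole
analysis is reproducible without any external data.

## The models

**Cell wall (TPP⁺ uptake).** Absorption is pseudo-second order with a
time-dependent coefficient that relaxes as PEF-induced wall pores reseal:

```
dN/dt = k_a(t) (N_m − N)(N_s − N),          N(0) = 0
k_a(t) = k_a0 + A e^(−Δt/τ_d) e^(−t/τ_d)
```

where `N` is the absorbed TPP⁺ amount (µM), `N_m` its saturation value,
`N_s` the pool concentration at the start of the slow stage, `k_a0` the
untreated (baseline) absorption coefficient, `A` the PEF pore-term
amplitude, `τ_d` the wall-pore lifetime, and `Δt` the delay between the
pulse and TPP⁺ addition. Because `k_a` depends only on time the ODE has the
closed form

```
N/N_m = (1 − S_Δt) / (1 − R·S_Δt),   R = N_m/N_s,
S_Δt = exp[(N_m − N_s)(k_a0·t + A·τ_d·e^(−Δt/τ_d)(1 − e^(−t/τ_d)))]
```

with the untreated baseline `N0/N_m` given by `A = 0`. Above a threshold
field the amplitude scales as
`A = b (E_p − E_th,p)² f² [1 − e^(−t_p/t_ch)]²`.

**Membrane (dye fluorescence).** `I(Δt) = I0·e^(−Δt/τ_l) + I_r`, with
`τ_l` the lipidic-pore decay time and `I_r` the residual intensity.

A fixed-step RK4 integrator of the uptake ODE serves as an independent
numerical oracle for the closed form (agreement ≤ 1e−6 relative).

## Worked example

Calibrate the model from the two printed anchors — untreated cells absorb
`N0/N_m = 0.12` of the maximal amount in 3 min, and cells probed immediately
after a 5.85 kV/cm pulse absorb `N/N_m = 0.65` — then generate one noisy
synthetic three-field recovery experiment and refit it:

```r
library(pefreseal)

constants <- uptake_constants(N_m = 0.5, N_s = 1.0)   # uM
cal <- calibrate_from_anchors(
  anchor_set(baseline_ratio = 0.12, delta0_ratio = 0.65,
             incubation_t = 180, tau_d = 24),
  constants)
cal$wall
#> Cell-wall pore parameters
#>   k_a0  = 0.000732866 1/(uM s)   (baseline absorption coefficient)
#>   A     = 0.0492624 1/(uM s)   (PEF pore-term amplitude)
#>   tau_d = 24 s          (wall pore lifetime)

fields <- c(2.93, 4.38, 5.85)                         # kV/cm
walls <- lapply(amplitudes_by_field(cal$A_reference, 5.85, fields),
                function(a) wall_pore_params(cal$k_a0, a, tau_d = 24))
g <- generate_uptake_dataset(constants, walls, fields,
                             noise = noise_spec(sigma = 0.03, seed = 1))
fit_uptake_recovery(g[[1]], constants, k_a0 = cal$k_a0)
#> Nonlinear least-squares fit (uptake model)
#>           estimate  std_error
#> tau_d  20.54100000 1.54517000
#> A_2.93  0.00317753 0.00157662
#> A_4.38  0.02542460 0.00377915
#> A_5.85  0.06598250 0.00961057
#>   n = 30 points, 4 parameters; R^2 = 0.96242, adj. R^2 = 0.9564
#>   converged: TRUE
```

The calibrated baseline coefficient is `k_a0 = 7.33e-4 1/(µM s)` and the
reference-field pore amplitude `A = 0.0493 1/(µM s)`: forward evaluation
reproduces both anchors exactly. A single noisy replicate recovers the
wall-pore lifetime to ~20.5 s against a generating truth of 24 s with one
amplitude per field, ordered with field strength; averaged over many
replicates the estimate centres on the truth (see the recovery functions).

A file-based pipeline (`run_simulate()`, `run_fit()`, `run_calibrate()`,
`run_recover()`) reads and writes delimited text with JSON manifests, and a
thin command-line wrapper ships in `inst/scripts/pef-kinetics.R`
(`simulate | fit-fluorescence | fit-uptake | calibrate | recover`).

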