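#' @keywords internal
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("pef_validation_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation("'", name, "' must be a single non-missing number")
  if (finite && !is.finite(x))
    stop_validation("'", name, "' must be finite")
  if (strict && x <= lower)
    stop_validation("'", name, "' must be > ", lower, " (got ", x, ")")
  if (!strict && x < lower)
    stop_validation("'", name, "' must be >= ", lower, " (got ", x, ")")
  invisible(x)
}

#' Pulse specification
#'
#' A square electric pulse applied to the cell suspension.
#'
#' @param E_p electric field strength, kV/cm (>= 0).
#' @param t_p pulse duration, microseconds (> 0). The experiments modelled
#'   here use 150 us pulses.
#' @return An object of class `pulse_spec`.
#' @examples
#' pulse_spec(E_p = 5.85, t_p = 150)
#' @export
pulse_spec <- function(E_p, t_p = 150) {
  check_scalar(E_p, "E_p", lower = 0)
  check_scalar(t_p, "t_p", lower = 0, strict = TRUE)
  structure(list(E_p = E_p, t_p = t_p), class = "pulse_spec")
}

#' Chemical constants of the uptake law
#'
#' Capacity and pool constants of the pseudo-second-order TPP+ absorption
#' model: `dN/dt = k_a(t) (N_m - N)(N_s - N)` with `N(0) = 0`.
#'
#' @param N_m maximal accumulable TPP+ amount, uM (> 0). The absorbed amount
#'   saturates at `N_m`.
#' @param N_s TPP+ pool concentration at the start of the slow-absorption
#'   stage, uM (> 0). The model requires `N_m < N_s`; the equal-roots limit
#'   `|N_m - N_s| < 1e-9 N_s` is handled by a continuous limiting solution.
#' @return An object of class `uptake_constants`.
#' @examples
#' uptake_constants(N_m = 0.5, N_s = 1.0)
#' @export
uptake_constants <- function(N_m = 0.5, N_s = 1.0) {
  check_scalar(N_m, "N_m", lower = 0, strict = TRUE)
  check_scalar(N_s, "N_s", lower = 0, strict = TRUE)
  if (N_m > N_s && abs(N_m - N_s) >= 1e-9 * N_s)
    stop_validation("'N_m' must not exceed 'N_s' (absorbed amount saturates below the pool)")
  structure(list(N_m = N_m, N_s = N_s), class = "uptake_constants")
}

#' Cell-wall pore parameters of the absorption coefficient
#'
#' The time-dependent absorption coefficient is
#' `k_a(t) = k_a0 + A exp(-t / tau_d)`: a baseline through the equilibrium
#' wall pores plus a transient excess from PEF-induced pores that reseal
#' with characteristic lifetime `tau_d`.
#'
#' @param k_a0 baseline absorption coefficient at E = 0, 1/(uM s) (>= 0).
#' @param A pore-term amplitude (the identifiable product of the pore-count
#'   constant and the initial excess pore amount), 1/(uM s) (>= 0).
#' @param tau_d characteristic lifetime of the PEF-induced wall pores,
#'   seconds (> 0).
#' @return An object of class `wall_pore_params`.
#' @examples
#' wall_pore_params(k_a0 = 7.329e-4, A = 0.0493, tau_d = 24)
#' @export
wall_pore_params <- function(k_a0, A = 0, tau_d = 24) {
  check_scalar(k_a0, "k_a0", lower = 0)
  check_scalar(A, "A", lower = 0)
  check_scalar(tau_d, "tau_d", lower = 0, strict = TRUE)
  structure(list(k_a0 = k_a0, A = A, tau_d = tau_d), class = "wall_pore_params")
}

#' Parametric field dependence of the pore amplitude
#'
#' Scales the pore-term amplitude with field strength as
#' `A = b (E_p - E_th_p)^2 f^2 [1 - exp(-t_p / t_ch)]^2` above the
#' permeabilization threshold `E_th_p`, and zero below it.
#'
#' @param b field-effectiveness constant, 1/(uM s (kV/cm)^2) (>= 0).
#' @param E_th_p threshold field strength, kV/cm (>= 0).
#' @param t_ch membrane charging time, microseconds (> 0).
#' @param f cell shape factor, dimensionless; 1.5 for spheres.
#' @return An object of class `field_response_params`.
#' @examples
#' field_response_params(b = 0.01, E_th_p = 2.0, t_ch = 1)
#' @export
field_response_params <- function(b, E_th_p = 2.0, t_ch = 1, f = 1.5) {
  check_scalar(b, "b", lower = 0)
  check_scalar(E_th_p, "E_th_p", lower = 0)
  check_scalar(t_ch, "t_ch", lower = 0, strict = TRUE)
  check_scalar(f, "f", lower = 0, strict = TRUE)
  structure(list(b = b, E_th_p = E_th_p, t_ch = t_ch, f = f),
            class = "field_response_params")
}

#' Membrane (lipidic pore) fluorescence decay parameters
#'
#' Fluorescence of a membrane-impermeant dye added a delay `delta_t` after
#' the pulse decays as `I(delta_t) = I0 exp(-delta_t / tau_l) + I_r`.
#'
#' @param I0 decaying amplitude at `delta_t = 0`, arbitrary fluorescence units
#'   (>= 0).
#' @param I_r residual intensity, same units (>= 0).
#' @param tau_l characteristic decay time of the lipidic pores, seconds (> 0).
#' @return An object of class `fluorescence_params`.
#' @examples
#' fluorescence_params(I0 = 100, I_r = 20, tau_l = 20)
#' @export
fluorescence_params <- function(I0 = 100, I_r = 20, tau_l = 20) {
  check_scalar(I0, "I0", lower = 0)
  check_scalar(I_r, "I_r", lower = 0)
  check_scalar(tau_l, "tau_l", lower = 0, strict = TRUE)
  structure(list(I0 = I0, I_r = I_r, tau_l = tau_l),
            class = "fluorescence_params")
}

#' Printed anchor ratios used for algebraic calibration
#'
#' The two dimensionless uptake ratios that pin down the baseline absorption
#' coefficient and the reference-field pore amplitude: the untreated
#' 3-minute absorption level `N0/N_m` and the zero-delay post-pulse level
#' `N/N_m` at the reference field strength.
#'
#' @param baseline_ratio untreated `N0/N_m` at `incubation_t` (in (0, 1)).
#' @param delta0_ratio `N/N_m` at `delta_t = 0` for the reference field
#'   (in (0, 1), strictly above `baseline_ratio`).
#' @param incubation_t incubation time after TPP+ addition, seconds.
#' @param tau_d assumed wall-pore lifetime used in the inversion, seconds.
#' @return An object of class `anchor_set`.
#' @examples
#' anchor_set(baseline_ratio = 0.12, delta0_ratio = 0.65)
#' @export
anchor_set <- function(baseline_ratio = 0.12, delta0_ratio = 0.65,
                       incubation_t = 180, tau_d = 24) {
  check_scalar(baseline_ratio, "baseline_ratio", lower = 0, strict = TRUE)
  check_scalar(delta0_ratio, "delta0_ratio", lower = 0, strict = TRUE)
  check_scalar(incubation_t, "incubation_t", lower = 0, strict = TRUE)
  check_scalar(tau_d, "tau_d", lower = 0, strict = TRUE)
  if (baseline_ratio >= 1 || delta0_ratio >= 1)
    stop_validation("anchor ratios must lie strictly inside (0, 1)")
  if (baseline_ratio >= delta0_ratio)
    stop_validation("'baseline_ratio' must be below 'delta0_ratio' (PEF increases uptake)")
  structure(list(baseline_ratio = baseline_ratio, delta0_ratio = delta0_ratio,
                 incubation_t = incubation_t, tau_d = tau_d),
            class = "anchor_set")
}

#' Additive-noise specification for the synthetic-data generators
#'
#' @param sigma standard deviation of the additive Gaussian noise, in the
#'   units of the generated series (>= 0).
#' @param seed integer master seed; replicate streams are drawn sequentially
#'   from it so a fixed seed reproduces every replicate.
#' @param n_replicates number of replicate series (>= 1).
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(sigma = 0.03, seed = 20191014, n_replicates = 100)
#' @export
noise_spec <- function(sigma = 0, seed = 20191014, n_replicates = 1) {
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(seed, "seed")
  check_scalar(n_replicates, "n_replicates", lower = 1)
  structure(list(sigma = sigma, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "noise_spec")
}

#' Stage structure of a simulated electrode trace
#'
#' The TPP+ electrode trace of an untreated suspension has three stages:
#' a fast adsorption drop (stage I), a delay plateau (stage II) and the slow
#' absorption (stage III). PEF treatment eliminates the delay stage, so
#' `pef_applied = TRUE` forces `stage2_duration = 0`.
#'
#' @param stage1_amplitude concentration drop of the fast adsorption stage, uM.
#' @param stage1_tau time constant of the fast stage, seconds (> 0).
#' @param stage2_duration length of the delay plateau, seconds (>= 0; must be
#'   0 when `pef_applied`).
#' @param pef_applied logical; was the suspension pulsed?
#' @return An object of class `trace_stage_spec`.
#' @examples
#' trace_stage_spec(stage1_amplitude = 0.15, stage1_tau = 3,
#'                  stage2_duration = 240, pef_applied = FALSE)
#' @export
trace_stage_spec <- function(stage1_amplitude = 0.15, stage1_tau = 3,
                             stage2_duration = 240, pef_applied = FALSE) {
  check_scalar(stage1_amplitude, "stage1_amplitude", lower = 0)
  check_scalar(stage1_tau, "stage1_tau", lower = 0, strict = TRUE)
  check_scalar(stage2_duration, "stage2_duration", lower = 0)
  if (!is.logical(pef_applied) || length(pef_applied) != 1L || is.na(pef_applied))
    stop_validation("'pef_applied' must be TRUE or FALSE")
  if (pef_applied && stage2_duration != 0)
    stop_validation("PEF eliminates the delay stage: 'stage2_duration' must be 0 when 'pef_applied'")
  structure(list(stage1_amplitude = stage1_amplitude, stage1_tau = stage1_tau,
                 stage2_duration = stage2_duration, pef_applied = pef_applied),
            class = "trace_stage_spec")
}

#' @export
print.wall_pore_params <- function(x, ...) {
  cat("Cell-wall pore parameters\n")
  cat(sprintf("  k_a0  = %.6g 1/(uM s)   (baseline absorption coefficient)\n", x$k_a0))
  cat(sprintf("  A     = %.6g 1/(uM s)   (PEF pore-term amplitude)\n", x$A))
  cat(sprintf("  tau_d = %.6g s          (wall pore lifetime)\n", x$tau_d))
  invisible(x)
}

#' @export
print.fluorescence_params <- function(x, ...) {
  cat("Membrane fluorescence decay parameters\n")
  cat(sprintf("  I0    = %.6g a.u.  I_r = %.6g a.u.  tau_l = %.6g s\n",
              x$I0, x$I_r, x$tau_l))
  invisible(x)
}
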