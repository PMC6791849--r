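# Shared fixtures: the calibrated study setup (anchors 0.12 / 0.65,
# N_s = 1 uM, N_m = 0.5 uM, 3-min incubation, tau_d = 24 s) and the
# delay/field grids of the two recovery designs.

study_constants <- function() uptake_constants(N_m = 0.5, N_s = 1.0)

study_calibration <- function(tau_d = 24) {
  calibrate_from_anchors(anchor_set(baseline_ratio = 0.12, delta0_ratio = 0.65,
                                    incubation_t = 180, tau_d = tau_d),
                         study_constants())
}

study_fields <- c(2.93, 4.38, 5.85)
uptake_delays <- c(5, 10, 20, 30, 40, 50, 60, 80, 120, 180)
fluor_delays <- c(10, 30, 90, 180, 360, 600)

study_walls <- function(tau_d = 24) {
  cal <- study_calibration(tau_d)
  A <- amplitudes_by_field(cal$A_reference, 5.85, study_fields)
  lapply(A, function(a) wall_pore_params(k_a0 = cal$k_a0, A = a, tau_d = tau_d))
}

# draw a random valid parameter set for property tests (rates in [0, 0.1],
# tau_d in [5, 100], N_m < N_s)
random_kinetics_params <- function() {
  N_s <- runif(1, 0.5, 2)
  N_m <- runif(1, 0.1, 0.95) * N_s
  list(constants = uptake_constants(N_m = N_m, N_s = N_s),
       wall = wall_pore_params(k_a0 = runif(1, 0, 0.1),
                               A = runif(1, 0, 0.1),
                               tau_d = runif(1, 5, 100)),
       delta_t = runif(1, 0, 120))
}
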