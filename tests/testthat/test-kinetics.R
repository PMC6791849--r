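# Closed-form kinetics: hand-checked values, boundary behaviour, limits.

test_that("pef_amplitude follows the quadratic-above-threshold charging law", {
  fr <- field_response_params(b = 0.01, E_th_p = 2.0, t_ch = 1, f = 1.5)
  # frozen from independent hand evaluation: 0.01 * 4 * 2.25 * (1 - e^-1)^2
  expect_equal(pef_amplitude(fr, pulse_spec(E_p = 4.0, t_p = 1)),
               0.01 * 4 * 2.25 * (1 - exp(-1))^2, tolerance = 1e-12)
  expect_equal(pef_amplitude(fr, pulse_spec(E_p = 4.0, t_p = 1)),
               0.0359619, tolerance = 1e-5)
  # at and below threshold: exactly zero excess pores
  expect_identical(pef_amplitude(fr, pulse_spec(E_p = 2.0, t_p = 150)), 0)
  expect_identical(pef_amplitude(fr, pulse_spec(E_p = 0.5, t_p = 150)), 0)
  # long-pulse saturation: bracket -> 1
  expect_equal(pef_amplitude(fr, pulse_spec(E_p = 4.0, t_p = 1e6)),
               0.01 * 4 * 2.25, tolerance = 1e-9)
  # monotone in field strength and duration
  amps_E <- vapply(seq(2, 8, by = 0.5), function(E)
    pef_amplitude(fr, pulse_spec(E, 150)), numeric(1))
  expect_true(all(diff(amps_E) >= 0))
  amps_t <- vapply(c(0.5, 1, 5, 50, 150), function(tp)
    pef_amplitude(fr, pulse_spec(4, tp)), numeric(1))
  expect_true(all(diff(amps_t) >= 0))
})

test_that("pore excess decays exponentially with the wall pore lifetime", {
  expect_equal(pore_excess(A = 0.3, tau_d = 24, t = 0), 0.3)
  expect_equal(pore_excess(A = 0.3, tau_d = 24, t = 24), 0.3 / exp(1))
  # frozen: A e^-2 at two lifetimes
  expect_equal(pore_excess(A = 0.049262, tau_d = 24, t = 48), 0.0066668,
               tolerance = 1e-4)
  expect_error(pore_excess(0.3, 24, t = -1), class = "pef_validation_error")
})

test_that("absorption rate is baseline plus decaying pore excess", {
  w <- wall_pore_params(k_a0 = 7.329e-4, A = 0.049262, tau_d = 24)
  # frozen: k_a0 + A/e
  expect_equal(absorption_rate(w, t = 24), 7.329e-4 + 0.049262 / exp(1),
               tolerance = 1e-12)
  expect_equal(absorption_rate(w, t = 24), 0.018855, tolerance = 1e-4)
  expect_equal(absorption_rate(w, t = 1e9), w$k_a0, tolerance = 1e-12)
  w0 <- wall_pore_params(k_a0 = 2e-3, A = 0, tau_d = 24)
  expect_equal(absorption_rate(w0, t = c(0, 10, 100)), rep(2e-3, 3))
  expect_true(all(absorption_rate(w, c(0, 5, 50, 500)) >= w$k_a0))
})

test_that("closed-form uptake reproduces the calibrated anchor ratios", {
  ct <- study_constants()
  # algebraic-inversion oracle frozen independently:
  # solve 0.12 = (1 - S0)/(1 - 0.5 S0)  =>  S0 = 0.88/0.94, k_a0 = -ln(S0)/90
  k_a0_oracle <- -log(0.88 / 0.94) / (0.5 * 180)
  expect_equal(k_a0_oracle, 7.329e-4, tolerance = 1e-4)
  w <- wall_pore_params(k_a0 = k_a0_oracle, A = 0, tau_d = 24)
  expect_equal(uptake_closed_form(ct, w, 180) / ct$N_m, 0.12, tolerance = 1e-10)
  expect_equal(baseline_uptake(ct, k_a0_oracle, 180), 0.12, tolerance = 1e-10)
  # boundary and limit behaviour
  expect_equal(uptake_closed_form(ct, w, 0), 0)
  expect_equal(uptake_closed_form(ct, w, 1e7), ct$N_m, tolerance = 1e-6)
  expect_equal(baseline_uptake(ct, k_a0 = 0, t = 180), 0)
  expect_equal(baseline_uptake(ct, k_a0_oracle, 1e7), 1, tolerance = 1e-6)
})

test_that("delayed uptake matches its frozen hand-evaluation chain", {
  ct <- study_constants()
  cal <- study_calibration()
  # frozen chain: S_dt = 0.86424 => ratio 0.23906
  expect_equal(uptake_with_delay(ct, cal$wall, t = 180, delta_t = 48),
               0.2391, tolerance = 2e-4)
  # delta_t = 0 reduces to the no-delay closed form
  expect_equal(uptake_with_delay(ct, cal$wall, 180, 0),
               uptake_closed_form(ct, cal$wall, 180) / ct$N_m,
               tolerance = 1e-12)
  # large-delay limit is the untreated baseline
  expect_equal(uptake_with_delay(ct, cal$wall, 180, 1e6),
               baseline_uptake(ct, cal$k_a0, 180), tolerance = 1e-12)
  expect_error(uptake_with_delay(ct, cal$wall, 180, -5),
               class = "pef_validation_error")
})

test_that("equal-roots degeneracy is handled continuously", {
  w <- wall_pore_params(k_a0 = 1e-3, A = 0.02, tau_d = 24)
  near <- uptake_constants(N_m = 1 - 1e-12, N_s = 1)
  equal <- uptake_constants(N_m = 1, N_s = 1)
  t <- c(10, 60, 180)
  expect_equal(uptake_closed_form(near, w, t), uptake_closed_form(equal, w, t),
               tolerance = 1e-6)
  # the limit solution solves dN/dt = k_a (N_m - N)^2: check against RK4
  ode <- integrate_uptake_ode(equal, w, 0, c(0, t))
  expect_equal(uptake_closed_form(equal, w, t), ode[-1], tolerance = 1e-6)
  expect_error(uptake_constants(N_m = 1.5, N_s = 1),
               class = "pef_validation_error")
})

test_that("fluorescence intensity decays exponentially to the residual", {
  p <- fluorescence_params(I0 = 100, I_r = 20, tau_l = 20)
  expect_equal(fluorescence_intensity(p, 0), 120)
  # frozen: 100/e + 20
  expect_equal(fluorescence_intensity(p, 20), 100 / exp(1) + 20,
               tolerance = 1e-12)
  expect_equal(fluorescence_intensity(p, 20), 56.788, tolerance = 1e-4)
  expect_equal(fluorescence_intensity(p, 1e9), 20, tolerance = 1e-9)
  dt <- seq(0, 600, by = 10)
  expect_true(all(diff(fluorescence_intensity(p, dt)) < 0))
  # decay by a factor e per lifetime; half-life tau_l ln 2
  i <- fluorescence_intensity(p, c(0, 20, 40)) - p$I_r
  expect_equal(i[1] / i[2], exp(1), tolerance = 1e-12)
  expect_equal(fluorescence_intensity(p, 20 * log(2)) - p$I_r, 50,
               tolerance = 1e-12)
  expect_error(fluorescence_intensity(p, -1), class = "pef_validation_error")
})

test_that("parameter constructors reject invalid values", {
  expect_error(wall_pore_params(k_a0 = -1e-3, A = 0, tau_d = 24),
               class = "pef_validation_error")
  expect_error(wall_pore_params(k_a0 = 1e-3, A = 0, tau_d = 0),
               class = "pef_validation_error")
  expect_error(field_response_params(b = -0.01), class = "pef_validation_error")
  expect_error(fluorescence_params(I0 = 100, I_r = -1, tau_l = 20),
               class = "pef_validation_error")
  expect_error(pulse_spec(E_p = -1), class = "pef_validation_error")
  expect_error(anchor_set(baseline_ratio = 0.7, delta0_ratio = 0.65),
               class = "pef_validation_error")
  expect_error(anchor_set(baseline_ratio = 0.12, delta0_ratio = 1.2),
               class = "pef_validation_error")
})
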