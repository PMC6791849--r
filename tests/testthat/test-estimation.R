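# Calibration algebra, least-squares fitting, goodness of fit, and the
# Monte-Carlo recovery machinery.

test_that("anchor calibration matches the independent algebraic oracle", {
  ct <- study_constants()
  cal <- study_calibration()
  # oracle: S0 = (1 - 0.12)/(1 - 0.5*0.12), k_a0 = -ln(S0)/(0.5*180)
  expect_equal(cal$k_a0, -log(0.88 / 0.94) / 90, tolerance = 1e-12)
  expect_equal(cal$k_a0, 7.329e-4, tolerance = 1e-4)
  # oracle: S = (1 - 0.65)/(1 - 0.5*0.65) = 0.51852, bracket inversion
  S <- 0.35 / 0.675
  A_oracle <- (-log(S) / 0.5 - cal$k_a0 * 180) / (24 * (1 - exp(-180 / 24)))
  expect_equal(cal$A_reference, A_oracle, tolerance = 1e-12)
  expect_equal(cal$A_reference, 0.049262, tolerance = 1e-4)
  # forward evaluation reproduces both anchors to 1e-10
  expect_equal(baseline_uptake(ct, cal$k_a0, 180), 0.12, tolerance = 1e-10)
  expect_equal(uptake_with_delay(ct, cal$wall, 180, 0), 0.65, tolerance = 1e-10)
  # cross-check k_a0 with an independent root-finder on the forward model
  k_root <- uniroot(function(k) baseline_uptake(ct, k, 180) - 0.12,
                    c(1e-6, 1e-2), tol = 1e-14)$root
  expect_equal(cal$k_a0, k_root, tolerance = 1e-8)
  # degenerate anchor pair: no PEF effect
  cal0 <- calibrate_from_anchors(anchor_set(0.12, 0.12 + 1e-12), ct)
  expect_equal(cal0$A_reference, 0, tolerance = 1e-9)
})

test_that("adjusted R-squared follows its definition", {
  expect_equal(adjusted_r_squared(1:10, 1:10, 2), 1)
  # predicted == mean: R^2 = 0, adj = 1 - 9/8
  expect_equal(adjusted_r_squared(1:10, rep(5.5, 10), 1), -0.125)
  # hand computation: SS_res = 0.04, SS_tot = 5, n = 4, p = 1
  expect_equal(adjusted_r_squared(1:4, c(1.1, 1.9, 3.1, 3.9), 1),
               1 - (1 - (1 - 0.04 / 5)) * 3 / 2, tolerance = 1e-12)
  expect_lte(adjusted_r_squared(1:10, 1:10 + 0.1, 2),
             r_squared(1:10, 1:10 + 0.1))
  expect_warning(r_squared(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(adjusted_r_squared(1:3, 1:3, 2), class = "pef_validation_error")
})

test_that("fluorescence fit recovers noiseless truth exactly", {
  p <- fluorescence_params(I0 = 100, I_r = 20, tau_l = 20)
  s <- fluorescence_series(fluor_delays, fluorescence_intensity(p, fluor_delays))
  fit <- fit_fluorescence_decay(s)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[c("I0", "I_r", "tau_l")]),
               c(100, 20, 20), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # randomized noiseless round trips
  set.seed(3)
  for (i in 1:10) {
    pr <- fluorescence_params(I0 = runif(1, 20, 200), I_r = runif(1, 0, 50),
                              tau_l = runif(1, 5, 120))
    sr <- fluorescence_series(fluor_delays,
                              fluorescence_intensity(pr, fluor_delays))
    fr <- fit_fluorescence_decay(sr)
    expect_equal(unname(fr$estimates),
                 c(pr$I0, pr$I_r, pr$tau_l), tolerance = 1e-5)
  }
})

test_that("degenerate fluorescence input is flagged, not silently fitted", {
  flat <- fluorescence_series(fluor_delays, rep(20, 6))
  fit <- fit_fluorescence_decay(flat)
  expect_false(fit$converged)
  expect_true("tau_l_unidentifiable" %in% fit$flags)
  expect_error(fit_fluorescence_decay(
    fluorescence_series(c(10, 30, 90), c(80, 45, 25))),
    class = "pef_validation_error")
})

test_that("uptake fit recovers noiseless truth, shared across fields", {
  ct <- study_constants()
  walls <- study_walls(tau_d = 24)
  datasets <- lapply(seq_along(study_fields), function(i)
    uptake_dataset(study_fields[i], uptake_delays,
                   uptake_with_delay(ct, walls[[i]], 180, uptake_delays)))
  fit <- fit_uptake_recovery(datasets, ct, k_a0 = walls[[1]]$k_a0)
  expect_true(fit$converged)
  # exactly one shared tau_d plus one amplitude per field
  expect_named(fit$estimates, c("tau_d", "A_2.93", "A_4.38", "A_5.85"))
  expect_equal(fit$estimates[["tau_d"]], 24, tolerance = 1e-6)
  a_true <- vapply(walls, `[[`, numeric(1), "A")
  expect_equal(unname(fit$estimates[-1]), unname(a_true), tolerance = 1e-5)
  # amplitude ordering follows the field strengths
  expect_true(fit$estimates[["A_5.85"]] > fit$estimates[["A_4.38"]])
  expect_true(fit$estimates[["A_4.38"]] > fit$estimates[["A_2.93"]])
  # single-field noiseless fit
  f1 <- fit_uptake_recovery(datasets[[3]], ct, k_a0 = walls[[1]]$k_a0)
  expect_equal(f1$estimates[["tau_d"]], 24, tolerance = 1e-6)
  # per-dataset lifetimes when not shared
  fi <- fit_uptake_recovery(datasets, ct, k_a0 = walls[[1]]$k_a0,
                            shared_tau_d = FALSE)
  expect_length(grep("^tau_d_", names(fi$estimates)), 3)
})

test_that("free-k_a0 mode recovers the baseline coefficient too", {
  ct <- study_constants()
  walls <- study_walls(tau_d = 24)
  datasets <- lapply(seq_along(study_fields), function(i)
    uptake_dataset(study_fields[i], uptake_delays,
                   uptake_with_delay(ct, walls[[i]], 180, uptake_delays)))
  fit <- fit_uptake_recovery(datasets, ct, k_a0 = 5e-4, fix_k_a0 = FALSE)
  expect_equal(fit$estimates[["k_a0"]], walls[[1]]$k_a0, tolerance = 1e-4)
  expect_equal(fit$estimates[["tau_d"]], 24, tolerance = 1e-4)
})

test_that("all-baseline data flags tau_d as unidentifiable", {
  ct <- study_constants()
  cal <- study_calibration()
  base <- baseline_uptake(ct, cal$k_a0, 180)
  set.seed(5)
  ds <- uptake_dataset(5.85, uptake_delays,
                       pmin(pmax(base + rnorm(10, 0, 0.01), 0), 1))
  fit <- fit_uptake_recovery(ds, ct, k_a0 = cal$k_a0)
  expect_lt(fit$estimates[["A_5.85"]], 0.01)
  expect_true("tau_d_unidentifiable" %in% fit$flags)
})

test_that("noisy Monte-Carlo recovery brackets the generating lifetimes", {
  # membrane: sigma = 2 a.u. on the six-delay design, truth tau_l = 20 s
  cfg_f <- list(model = "fluorescence",
                params = fluorescence_params(100, 20, 20),
                noise = noise_spec(sigma = 2, seed = 20191014,
                                   n_replicates = 100))
  sf <- recovery_experiment(cfg_f)
  tau_l_row <- sf[sf$parameter == "tau_l", ]
  expect_gt(tau_l_row$mean_estimate, 18)
  expect_lt(tau_l_row$mean_estimate, 22)
  # wall: sigma = 0.03 on the ten-delay, three-field design, truth 24 s
  cfg_u <- list(model = "uptake", constants = study_constants(),
                wall_by_field = study_walls(24), fields = study_fields,
                noise = noise_spec(sigma = 0.03, seed = 20191014,
                                   n_replicates = 100))
  su <- recovery_experiment(cfg_u)
  tau_d_row <- su[su$parameter == "tau_d", ]
  expect_lt(abs(tau_d_row$bias), 2)
  expect_true(all(c("A_2.93", "A_4.38", "A_5.85") %in% su$parameter))
})

test_that("recovery experiment is deterministic, unbiased at zero noise, and monotone in noise", {
  cfg <- list(model = "fluorescence", params = fluorescence_params(100, 20, 20),
              noise = noise_spec(sigma = 0, seed = 1, n_replicates = 3))
  s0 <- recovery_experiment(cfg)
  expect_true(all(abs(s0$bias) < 1e-6))
  cfg$noise <- noise_spec(sigma = 2, seed = 99, n_replicates = 20)
  s1 <- recovery_experiment(cfg)
  s1b <- recovery_experiment(cfg)
  expect_identical(s1, s1b)
  cfg$noise <- noise_spec(sigma = 4, seed = 99, n_replicates = 20)
  s2 <- recovery_experiment(cfg)
  expect_gte(s2[s2$parameter == "tau_l", "rmse"],
             s1[s1$parameter == "tau_l", "rmse"])
  expect_error(recovery_experiment(list(model = "fluorescence",
                                        params = fluorescence_params(),
                                        noise = noise_spec(n_replicates = 1))),
               class = "pef_validation_error")
})
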