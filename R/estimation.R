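# Nonlinear least-squares estimation of the resealing time constants, the
# algebraic anchor calibration, and goodness-of-fit statistics.

#' Uptake-recovery dataset
#'
#' One field strength's series of absorbed fractions measured when TPP+ was
#' added `delta_t` seconds after the pulse and incubated for `incubation_t`
#' seconds.
#'
#' @param field_strength electric field strength, kV/cm.
#' @param delta_t post-pulse delays, seconds (strictly increasing, >= 0).
#' @param ratio absorbed fractions `N/N_m`, each in `[0, 1]`.
#' @param incubation_t incubation time, seconds. The experiments modelled
#'   here use 180 s (3 min).
#' @return A `data.frame` of class `uptake_dataset` with columns `delta_t`
#'   and `ratio` and attributes `field_strength`, `incubation_t`.
#' @examples
#' uptake_dataset(5.85, delta_t = c(5, 60, 180), ratio = c(0.6, 0.2, 0.13))
#' @export
uptake_dataset <- function(field_strength, delta_t, ratio, incubation_t = 180) {
  check_scalar(field_strength, "field_strength", lower = 0)
  check_scalar(incubation_t, "incubation_t", lower = 0, strict = TRUE)
  if (length(delta_t) != length(ratio))
    stop_validation("'delta_t' and 'ratio' must have equal length")
  if (any(!is.finite(delta_t) | delta_t < 0) || any(diff(delta_t) <= 0))
    stop_validation("'delta_t' must be non-negative and strictly increasing")
  if (any(!is.finite(ratio) | ratio < 0 | ratio > 1))
    stop_validation("'ratio' values must lie in [0, 1]")
  structure(data.frame(delta_t = delta_t, ratio = ratio),
            field_strength = field_strength, incubation_t = incubation_t,
            class = c("uptake_dataset", "data.frame"))
}

#' Fluorescence decay series
#'
#' @param delta_t dye-addition delays, seconds (strictly increasing, >= 0).
#' @param intensity fluorescence intensities, arbitrary units.
#' @param replicate_id optional replicate label.
#' @return A `data.frame` of class `fluorescence_series`.
#' @examples
#' fluorescence_series(c(10, 30, 90, 180, 360, 600), c(80, 45, 22, 20, 20, 20))
#' @export
fluorescence_series <- function(delta_t, intensity, replicate_id = NA_character_) {
  if (length(delta_t) != length(intensity))
    stop_validation("'delta_t' and 'intensity' must have equal length")
  if (any(!is.finite(delta_t) | delta_t < 0) || any(diff(delta_t) <= 0))
    stop_validation("'delta_t' must be non-negative and strictly increasing")
  if (any(!is.finite(intensity)))
    stop_validation("'intensity' must be finite")
  structure(data.frame(delta_t = delta_t, intensity = intensity),
            replicate_id = replicate_id,
            class = c("fluorescence_series", "data.frame"))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`. Returns `NA` with a warning when the
#' observations have zero total variance (the statistic is undefined).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return `R^2`, dimensionless.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop_validation("'observed' and 'predicted' must have equal length")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("zero total variance: R^2 is undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`, penalizing the parameter count
#' `p`. Requires `n > p + 1`.
#'
#' @param observed,predicted numeric vectors of equal length `n`.
#' @param n_params number of fitted parameters `p`.
#' @return Adjusted `R^2`, dimensionless; always `<=` the plain `R^2`.
#' @examples
#' adjusted_r_squared(1:4, c(1.1, 1.9, 3.1, 3.9), n_params = 1)
#' @export
adjusted_r_squared <- function(observed, predicted, n_params) {
  n <- length(observed)
  check_scalar(n_params, "n_params", lower = 0)
  if (n <= n_params + 1)
    stop_validation("adjusted R^2 needs more points than parameters + 1")
  r2 <- r_squared(observed, predicted)
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

# Assemble a FitResult.
new_fit_result <- function(estimates, std_errors, observed, predicted,
                           converged, flags = character(), model = "") {
  n <- length(observed)
  p <- length(estimates)
  r2 <- if (n > 0) suppressWarnings(r_squared(observed, predicted)) else NA_real_
  adj <- if (n > p + 1 && !is.na(r2))
    1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  structure(list(estimates = estimates, std_errors = std_errors,
                 r_squared = r2, adj_r_squared = adj,
                 n_points = n, n_params = p, converged = converged,
                 residuals = observed - predicted, flags = flags,
                 model = model),
            class = "pef_fit")
}

#' @export
print.pef_fit <- function(x, ...) {
  cat(sprintf("Nonlinear least-squares fit (%s model)\n", x$model))
  est <- data.frame(estimate = x$estimates,
                    std_error = x$std_errors[names(x$estimates)])
  print(signif(est, 6))
  cat(sprintf("  n = %d points, %d parameters; R^2 = %.5g, adj. R^2 = %.5g\n",
              x$n_points, x$n_params, x$r_squared, x$adj_r_squared))
  cat(sprintf("  converged: %s%s\n", x$converged,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# Standard errors from a minpack.lm fit: s^2 (J'J)^-1. NA when the Jacobian
# is rank deficient (unidentifiable parameters).
lm_std_errors <- function(fit, n, p) {
  se <- rep(NA_real_, p)
  if (n > p) {
    s2 <- fit$deviance / (n - p)
    covm <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
    if (!is.null(covm)) {
      d <- diag(covm)
      se <- ifelse(d >= 0, sqrt(d), NA_real_)
    }
  }
  se
}

#' Fit the exponential fluorescence decay
#'
#' Least-squares estimation of `(I0, I_r, tau_l)` in
#' `I(delta_t) = I0 exp(-delta_t/tau_l) + I_r` by bounded
#' Levenberg-Marquardt. Starting values come from the series itself
#' (residual level from the tail, decay time from a log-linear fit) unless
#' an explicit guess is supplied, so the fit is deterministic given the data.
#'
#' @param series a [fluorescence_series()] or a data.frame with columns
#'   `delta_t` and `intensity`.
#' @param initial_guess optional [fluorescence_params()] starting point.
#' @return A `pef_fit` result with estimates `I0`, `I_r`, `tau_l` (units
#'   a.u., a.u., s), standard errors, `R^2` and adjusted `R^2`. A series
#'   with no decay signal is flagged (`converged = FALSE`,
#'   `"tau_l_unidentifiable"`), never silently returned.
#' @examples
#' p <- fluorescence_params(100, 20, 20)
#' s <- fluorescence_series(c(10, 30, 90, 180, 360, 600),
#'                          fluorescence_intensity(p, c(10, 30, 90, 180, 360, 600)))
#' fit_fluorescence_decay(s)$estimates
#' @export
fit_fluorescence_decay <- function(series, initial_guess = NULL) {
  if (!is.data.frame(series) || !all(c("delta_t", "intensity") %in% names(series)))
    stop_validation("'series' must have columns 'delta_t' and 'intensity'")
  dt <- series$delta_t
  y <- series$intensity
  if (length(unique(dt)) < 4L)
    stop_validation("need at least 4 distinct delays to fit 3 parameters")
  if (stats::sd(y) == 0) {
    est <- c(I0 = 0, I_r = y[1], tau_l = NA_real_)
    return(new_fit_result(est, c(I0 = NA_real_, I_r = NA_real_, tau_l = NA_real_),
                          y, rep(y[1], length(y)), converged = FALSE,
                          flags = "tau_l_unidentifiable", model = "fluorescence"))
  }
  if (is.null(initial_guess)) {
    ir0 <- min(y)
    amp0 <- max(y) - ir0
    pos <- y - ir0 > 0.05 * amp0
    tau0 <- 0.5 * max(dt)
    if (sum(pos) >= 2) {
      sl <- stats::coef(stats::lm(log(y[pos] - ir0 + 1e-12) ~ dt[pos]))[2]
      if (is.finite(sl) && sl < 0) tau0 <- min(max(-1 / sl, 1e-2), 1e4)
    }
    start <- c(I0 = max(amp0, 1e-6), I_r = ir0, tau_l = tau0)
  } else {
    stopifnot(inherits(initial_guess, "fluorescence_params"))
    start <- c(I0 = initial_guess$I0, I_r = initial_guess$I_r,
               tau_l = initial_guess$tau_l)
  }
  resid_fn <- function(p) p[1] * exp(-dt / p[3]) + p[2] - y
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(0, 0, 1e-3), upper = c(Inf, Inf, 1e4),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  est <- stats::setNames(fit$par, c("I0", "I_r", "tau_l"))
  pred <- est[["I0"]] * exp(-dt / est[["tau_l"]]) + est[["I_r"]]
  se <- stats::setNames(lm_std_errors(fit, length(y), 3L), names(est))
  converged <- fit$info %in% 1:3
  flags <- character()
  if (is.na(se[["tau_l"]]) || (is.finite(se[["I0"]]) && est[["I0"]] < 2 * se[["I0"]])) {
    flags <- "tau_l_unidentifiable"
    converged <- FALSE
  }
  new_fit_result(est, se, y, pred, converged, flags, model = "fluorescence")
}

#' Fit the uptake-recovery model across field strengths
#'
#' Least-squares fit of the delayed-uptake closed form
#' `N/N_m = (1 - S_dt)/(1 - R S_dt)` to one or more per-field datasets, with
#' one pore-term amplitude `A` per field and (by default) a single shared
#' wall-pore lifetime `tau_d`. The baseline coefficient `k_a0` is fixed at
#' the supplied value by default — the untreated absorption level is measured
#' separately in this design — or can be freed with `fix_k_a0 = FALSE`.
#'
#' @param datasets a single [uptake_dataset()] or a list of them.
#' @param constants an [uptake_constants()] object.
#' @param k_a0 baseline absorption coefficient, 1/(uM s) (fixed value, or
#'   starting value when `fix_k_a0 = FALSE`).
#' @param shared_tau_d logical; fit one `tau_d` across all datasets
#'   (default) or one per dataset.
#' @param fix_k_a0 logical; keep `k_a0` fixed (default) or estimate it.
#' @param tau_d_init starting value for `tau_d`, seconds.
#' @return A `pef_fit` with estimates `tau_d` (or `tau_d_<field>`) and one
#'   `A_<field>` per dataset, plus `k_a0` when freed. When every amplitude
#'   is within 2 standard errors of 0 (no detectable PEF signal) the result
#'   carries the flag `"tau_d_unidentifiable"`.
#' @examples
#' ct <- uptake_constants()
#' w  <- wall_pore_params(k_a0 = 7.329e-4, A = 0.0493, tau_d = 24)
#' dt <- c(5, 10, 20, 30, 40, 50, 60, 80, 120, 180)
#' ds <- uptake_dataset(5.85, dt, uptake_with_delay(ct, w, 180, dt))
#' fit_uptake_recovery(ds, ct, k_a0 = 7.329e-4)$estimates
#' @export
fit_uptake_recovery <- function(datasets, constants, k_a0,
                                shared_tau_d = TRUE, fix_k_a0 = TRUE,
                                tau_d_init = 30) {
  if (inherits(datasets, "uptake_dataset")) datasets <- list(datasets)
  if (!length(datasets) || !all(vapply(datasets, inherits, TRUE, "uptake_dataset")))
    stop_validation("'datasets' must be one or more uptake_dataset objects")
  stopifnot(inherits(constants, "uptake_constants"))
  check_scalar(k_a0, "k_a0", lower = 0)
  nd <- length(datasets)
  fields <- vapply(datasets, attr, numeric(1), "field_strength")
  t_inc <- vapply(datasets, attr, numeric(1), "incubation_t")
  f_lab <- formatC(fields, format = "g")

  # starting amplitudes by algebraic inversion at the smallest delay
  a_init <- vapply(seq_len(nd), function(i) {
    d <- datasets[[i]]
    r <- min(max(d$ratio[1], 1e-6), 1 - 1e-6)
    K <- invert_ratio_to_integral(constants, r)
    a <- (K - k_a0 * t_inc[i]) /
      (tau_d_init * exp(-d$delta_t[1] / tau_d_init) *
         (1 - exp(-t_inc[i] / tau_d_init)))
    max(a, 1e-6)
  }, numeric(1))

  tau_names <- if (shared_tau_d) "tau_d" else paste0("tau_d_", f_lab)
  par <- c(stats::setNames(rep(tau_d_init, length(tau_names)), tau_names),
           stats::setNames(a_init, paste0("A_", f_lab)))
  if (!fix_k_a0) par <- c(par, k_a0 = max(k_a0, 1e-8))
  lower <- ifelse(grepl("^tau_d", names(par)), 1e-2, 0)
  upper <- ifelse(grepl("^tau_d", names(par)), 1e4, Inf)

  obs <- unlist(lapply(datasets, `[[`, "ratio"))
  resid_fn <- function(p) {
    ka0 <- if (fix_k_a0) k_a0 else p[["k_a0"]]
    unlist(lapply(seq_len(nd), function(i) {
      tau <- if (shared_tau_d) p[["tau_d"]] else p[[paste0("tau_d_", f_lab[i])]]
      w <- wall_pore_params(k_a0 = ka0, A = p[[paste0("A_", f_lab[i])]],
                            tau_d = tau)
      uptake_with_delay(constants, w, t_inc[i], datasets[[i]]$delta_t) -
        datasets[[i]]$ratio
    }))
  }
  fit <- minpack.lm::nls.lm(par = par, fn = resid_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  est <- stats::setNames(fit$par, names(par))
  pred <- obs + resid_fn(est)  # resid = pred - obs
  se <- stats::setNames(lm_std_errors(fit, length(obs), length(par)), names(par))
  converged <- fit$info %in% 1:3
  flags <- character()
  a_idx <- grep("^A_", names(est))
  weak <- is.na(se[a_idx]) | est[a_idx] < 2 * se[a_idx]
  if (all(weak)) flags <- c(flags, "tau_d_unidentifiable")
  else if (any(weak))
    flags <- c(flags, paste0("amplitude_weak_", f_lab[weak]))
  new_fit_result(est, se, obs, pred, converged, flags, model = "uptake")
}

# Invert a ratio r = (1 - S)/(1 - R S) to the accumulated rate integral K.
invert_ratio_to_integral <- function(constants, ratio) {
  N_m <- constants$N_m
  N_s <- constants$N_s
  if (abs(N_m - N_s) < EQUAL_ROOTS_TOL * N_s)
    return(ratio / (N_m * (1 - ratio)))
  R <- N_m / N_s
  S <- (1 - ratio) / (1 - R * ratio)
  log(S) / (N_m - N_s)
}

#' Calibrate the uptake model from printed anchor ratios
#'
#' Algebraically inverts the closed-form model against two anchors: the
#' untreated 3-minute baseline fraction fixes `k_a0` through
#' `S0 = (1 - r0)/(1 - R r0)`, `k_a0 = ln(S0) / ((N_m - N_s) t)`, and the
#' zero-delay post-pulse fraction at the reference field then fixes the
#' pore amplitude `A` through the delayed-uptake factor. Forward evaluation
#' of the calibrated model reproduces both anchors to better than 1e-10.
#'
#' @param anchors an [anchor_set()] object.
#' @param constants an [uptake_constants()] object with `N_m < N_s`.
#' @return A list with `k_a0` and `A_reference` (both 1/(uM s)), plus the
#'   `wall` ([wall_pore_params()]) they imply for the reference field.
#' @examples
#' cal <- calibrate_from_anchors(anchor_set(0.12, 0.65), uptake_constants())
#' cal$k_a0        # 7.329e-4
#' cal$A_reference # 0.049262
#' @export
calibrate_from_anchors <- function(anchors, constants) {
  stopifnot(inherits(anchors, "anchor_set"),
            inherits(constants, "uptake_constants"))
  t <- anchors$incubation_t
  K0 <- invert_ratio_to_integral(constants, anchors$baseline_ratio)
  k_a0 <- K0 / t
  K1 <- invert_ratio_to_integral(constants, anchors$delta0_ratio)
  A <- (K1 - k_a0 * t) / (anchors$tau_d * (1 - exp(-t / anchors$tau_d)))
  A <- max(A, 0)
  list(k_a0 = k_a0, A_reference = A,
       wall = wall_pore_params(k_a0 = k_a0, A = A, tau_d = anchors$tau_d))
}

#' Spread a reference pore amplitude over field strengths
#'
#' Uses the quadratic-above-threshold field-response law to scale a
#' calibrated reference amplitude to other field strengths: `b` is solved
#' from `A_reference` at `E_reference` and the law is then evaluated at each
#' field. With a common pulse duration the charging factor cancels, so the
#' scaling is `A_E = A_reference (E - E_th_p)^2 / (E_ref - E_th_p)^2`.
#'
#' @param A_reference calibrated amplitude at the reference field, 1/(uM s).
#' @param E_reference reference field strength, kV/cm.
#' @param fields field strengths to scale to, kV/cm.
#' @param field_response a [field_response_params()] object whose `b` is
#'   ignored (solved internally); its threshold, charging time and shape
#'   factor are used.
#' @param pulse a [pulse_spec()] shared by all fields.
#' @return Named numeric vector of amplitudes, one per field.
#' @examples
#' amplitudes_by_field(0.049262, 5.85, c(2.93, 4.38, 5.85))
#' @export
amplitudes_by_field <- function(A_reference, E_reference, fields,
                                field_response = field_response_params(b = 1),
                                pulse = pulse_spec(E_p = E_reference, t_p = 150)) {
  check_scalar(A_reference, "A_reference", lower = 0)
  fr1 <- field_response_params(b = 1, E_th_p = field_response$E_th_p,
                               t_ch = field_response$t_ch, f = field_response$f)
  ref_shape <- pef_amplitude(fr1, pulse_spec(E_p = E_reference, t_p = pulse$t_p))
  if (ref_shape <= 0)
    stop_validation("'E_reference' must be above the threshold field strength")
  b <- A_reference / ref_shape
  out <- vapply(fields, function(E) {
    b * pef_amplitude(fr1, pulse_spec(E_p = E, t_p = pulse$t_p))
  }, numeric(1))
  stats::setNames(out, formatC(fields, format = "g"))
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeatedly generates synthetic data at known parameter values, refits the
#' model, and summarizes estimator quality per parameter: mean estimate,
#' bias, RMSE, and 95% Wald coverage. Deterministic given the seed.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{model}{`"uptake"` or `"fluorescence"`.}
#'     \item{noise}{a [noise_spec()] (its `n_replicates` is the replicate
#'       count, >= 2).}
#'     \item{...}{for `"fluorescence"`: `params` ([fluorescence_params()])
#'       and optional `delta_t_grid`. For `"uptake"`: `constants`,
#'       `wall_by_field` (named list of [wall_pore_params()]), `fields`,
#'       optional `delta_t_grid` and `incubation_t`.}
#'   }
#' @return A `data.frame` with one row per recovered parameter: `parameter`,
#'   `true`, `mean_estimate`, `bias`, `rmse`, `sd`, `coverage95`,
#'   `n_replicates`; attribute `n_converged` counts usable replicate fits.
#' @examples
#' cfg <- list(model = "fluorescence", params = fluorescence_params(100, 20, 20),
#'             noise = noise_spec(sigma = 2, seed = 1, n_replicates = 5))
#' recovery_experiment(cfg)
#' @export
recovery_experiment <- function(config) {
  if (!is.list(config) || is.null(config$model) || is.null(config$noise))
    stop_validation("'config' must name a model and a noise_spec")
  noise <- config$noise
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$n_replicates < 2)
    stop_validation("recovery experiments need at least 2 replicates")

  if (config$model == "fluorescence") {
    params <- config$params
    stopifnot(inherits(params, "fluorescence_params"))
    grid <- config$delta_t_grid %||% c(10, 30, 90, 180, 360, 600)
    reps <- generate_fluorescence_series(params, grid, noise)
    fits <- lapply(reps, fit_fluorescence_decay)
    truth <- c(I0 = params$I0, I_r = params$I_r, tau_l = params$tau_l)
  } else if (config$model == "uptake") {
    constants <- config$constants
    wall_by_field <- config$wall_by_field
    fields <- config$fields
    grid <- config$delta_t_grid %||% c(5, 10, 20, 30, 40, 50, 60, 80, 120, 180)
    t_inc <- config$incubation_t %||% 180
    reps <- generate_uptake_dataset(constants, wall_by_field, fields, grid,
                                    t_inc, noise)
    k_a0 <- wall_by_field[[1]]$k_a0
    fits <- lapply(reps, fit_uptake_recovery, constants = constants,
                   k_a0 = k_a0, shared_tau_d = TRUE)
    truth <- c(tau_d = wall_by_field[[1]]$tau_d,
               stats::setNames(vapply(wall_by_field, `[[`, numeric(1), "A"),
                               paste0("A_", formatC(fields, format = "g"))))
  } else {
    stop_validation("unknown model '", config$model, "'")
  }

  ok <- vapply(fits, function(f)
    all(is.finite(f$estimates[names(truth)])), logical(1))
  est <- do.call(rbind, lapply(fits[ok], function(f) f$estimates[names(truth)]))
  ses <- do.call(rbind, lapply(fits[ok], function(f) f$std_errors[names(truth)]))
  summary <- data.frame(
    parameter = names(truth),
    true = unname(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(truth),
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
    sd = apply(est, 2, stats::sd),
    coverage95 = vapply(seq_along(truth), function(j) {
      covered <- abs(est[, j] - truth[j]) <= 1.96 * ses[, j]
      mean(covered, na.rm = TRUE)
    }, numeric(1)),
    n_replicates = noise$n_replicates,
    row.names = NULL)
  attr(summary, "n_converged") <- sum(ok)
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
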