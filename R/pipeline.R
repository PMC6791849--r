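# File-based pipeline: validated run configurations, delimited-text I/O at
# full precision, and the simulate / fit / calibrate / recover commands that
# the command-line wrapper (inst/scripts/pef-kinetics.R) dispatches to.

PEF_CONFIG_KEYS <- list(
  simulate = c("design", "out_dir", "seed", "sigma", "n_replicates",
               "I0", "I_r", "tau_l", "delta_t_grid",
               "N_m", "N_s", "baseline_ratio", "delta0_ratio", "tau_d",
               "fields", "E_reference", "E_th_p", "incubation_t",
               "stage1_amplitude", "stage1_tau", "stage2_duration",
               "pef_applied", "t_max", "t_step", "log_level"),
  fit = c("type", "inputs", "out_dir", "N_m", "N_s", "k_a0",
          "shared_tau_d", "fix_k_a0", "log_level"),
  calibrate = c("out_dir", "baseline_ratio", "delta0_ratio", "incubation_t",
                "tau_d", "N_m", "N_s", "log_level"),
  recover = c("model", "out_dir", "seed", "sigma", "n_replicates",
              "I0", "I_r", "tau_l", "delta_t_grid",
              "N_m", "N_s", "baseline_ratio", "delta0_ratio", "tau_d",
              "fields", "E_reference", "E_th_p", "incubation_t", "log_level")
)

#' Validate a pipeline run configuration
#'
#' Checks that a configuration list only uses keys known to the given
#' command and that the required keys are present. Unknown keys are
#' rejected rather than ignored, so typos cannot silently change a run.
#'
#' @param config a named list (e.g. read from a YAML file).
#' @param command one of `"simulate"`, `"fit"`, `"calibrate"`, `"recover"`.
#' @return The config, invisibly; signals a validation error otherwise.
#' @export
validate_run_config <- function(config, command) {
  if (!command %in% names(PEF_CONFIG_KEYS))
    stop_validation("unknown command '", command, "'")
  if (!is.list(config))
    stop_validation("'config' must be a named list")
  unknown <- setdiff(names(config), PEF_CONFIG_KEYS[[command]])
  if (length(unknown))
    stop_validation("unknown config key(s) for '", command, "': ",
                    paste(unknown, collapse = ", "))
  required <- switch(command,
                     simulate = c("design", "out_dir"),
                     fit = c("type", "inputs", "out_dir"),
                     calibrate = "out_dir",
                     recover = c("model", "out_dir"))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop_validation("missing required config key(s) for '", command, "': ",
                    paste(missing, collapse = ", "))
  invisible(config)
}

pef_log <- function(config, ...) {
  lvl <- config$log_level %||% "info"
  if (identical(lvl, "quiet")) return(invisible())
  message("[pefreseal] ", ...)
}

# Full-precision delimited text: >= 15 significant digits so numeric
# round-trips are lossless.
write_precise_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

read_checked_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop_validation("input file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_validation("cannot parse '", path,
                                                     "': ", conditionMessage(e)))
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop_validation("file '", path, "' lacks column(s): ",
                    paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_validation("file '", path, "' has no data rows")
  for (col in required_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop_validation("file '", path, "', column '", col, "': non-numeric ",
                      "value at data row ", bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

write_manifest <- function(out_dir, manifest, name = "manifest.json") {
  jsonlite::write_json(manifest, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

resolve_and_record <- function(config, command) {
  validate_run_config(config, command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config
}

# Calibrated study defaults shared by simulate and recover: anchor ratios
# 0.12 / 0.65, tau_d 24 s, three fields, reference field 5.85 kV/cm.
uptake_study_setup <- function(config) {
  constants <- uptake_constants(N_m = config$N_m %||% 0.5,
                                N_s = config$N_s %||% 1.0)
  anchors <- anchor_set(baseline_ratio = config$baseline_ratio %||% 0.12,
                        delta0_ratio = config$delta0_ratio %||% 0.65,
                        incubation_t = config$incubation_t %||% 180,
                        tau_d = config$tau_d %||% 24)
  cal <- calibrate_from_anchors(anchors, constants)
  fields <- config$fields %||% c(2.93, 4.38, 5.85)
  E_ref <- config$E_reference %||% 5.85
  fr <- field_response_params(b = 1, E_th_p = config$E_th_p %||% 2.0)
  A_by_field <- amplitudes_by_field(cal$A_reference, E_ref, fields, fr)
  wall_by_field <- lapply(A_by_field, function(a)
    wall_pore_params(k_a0 = cal$k_a0, A = a, tau_d = anchors$tau_d))
  list(constants = constants, anchors = anchors, cal = cal, fields = fields,
       A_by_field = A_by_field, wall_by_field = wall_by_field,
       delta_t_grid = config$delta_t_grid %||% c(5, 10, 20, 30, 40, 50, 60, 80, 120, 180),
       incubation_t = anchors$incubation_t)
}

#' Simulate one of the three experimental designs to disk
#'
#' Writes delimited-text dataset(s) plus a JSON manifest of the generator
#' parameters into `config$out_dir`. Designs: `"uptake"` (one CSV per field
#' strength on the 5-180 s delay grid), `"fluorescence"` (one CSV, six
#' delays per replicate), `"trace"` (one CSV electrode trace). Identical
#' config and seed give byte-identical files.
#'
#' @param config a validated run configuration; see
#'   [validate_run_config()]. Unset parameters fall back to the calibrated
#'   study defaults.
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config) {
  config <- resolve_and_record(config, "simulate")
  noise <- noise_spec(sigma = config$sigma %||% 0,
                      seed = config$seed %||% 20191014,
                      n_replicates = config$n_replicates %||% 1)
  out <- config$out_dir
  paths <- character()
  if (config$design == "fluorescence") {
    params <- fluorescence_params(I0 = config$I0 %||% 100,
                                  I_r = config$I_r %||% 20,
                                  tau_l = config$tau_l %||% 20)
    grid <- config$delta_t_grid %||% c(10, 30, 90, 180, 360, 600)
    reps <- generate_fluorescence_series(params, grid, noise)
    df <- do.call(rbind, lapply(seq_along(reps), function(i)
      data.frame(replicate = i, delta_t_s = reps[[i]]$delta_t,
                 intensity_au = reps[[i]]$intensity)))
    paths <- write_precise_csv(df, file.path(out, "fluorescence.csv"))
    write_manifest(out, list(design = "fluorescence", parameters = unclass(params),
                             delta_t_grid = grid, noise = unclass(noise)))
  } else if (config$design == "uptake") {
    setup <- uptake_study_setup(config)
    reps <- generate_uptake_dataset(setup$constants, setup$wall_by_field,
                                    setup$fields, setup$delta_t_grid,
                                    setup$incubation_t, noise)
    paths <- vapply(seq_along(setup$fields), function(i) {
      f <- setup$fields[i]
      df <- do.call(rbind, lapply(seq_along(reps), function(r) {
        d <- reps[[r]][[i]]
        data.frame(replicate = r, field_kV_cm = f, delta_t_s = d$delta_t,
                   ratio = d$ratio)
      }))
      write_precise_csv(df, file.path(out, sprintf("uptake_E%s.csv",
                                                   formatC(f, format = "g"))))
    }, character(1))
    write_manifest(out, list(
      design = "uptake",
      constants = unclass(setup$constants),
      k_a0 = setup$cal$k_a0, tau_d = setup$anchors$tau_d,
      A_by_field = as.list(setup$A_by_field),
      fields = setup$fields, delta_t_grid = setup$delta_t_grid,
      incubation_t = setup$incubation_t, noise = unclass(noise)))
  } else if (config$design == "trace") {
    constants <- uptake_constants(N_m = config$N_m %||% 0.5,
                                  N_s = config$N_s %||% 1.0)
    cal <- calibrate_from_anchors(anchor_set(), constants)
    pef <- isTRUE(config$pef_applied)
    stages <- trace_stage_spec(
      stage1_amplitude = config$stage1_amplitude %||% 0.15,
      stage1_tau = config$stage1_tau %||% 3,
      stage2_duration = if (pef) 0 else config$stage2_duration %||% 240,
      pef_applied = pef)
    wall <- wall_pore_params(k_a0 = cal$k_a0,
                             A = if (pef) cal$A_reference else 0,
                             tau_d = config$tau_d %||% 24)
    grid <- seq(0, config$t_max %||% 600, by = config$t_step %||% 1)
    tr <- generate_electrode_trace(constants, wall, stages, grid, noise)
    df <- data.frame(time_s = tr$time, concentration_uM = tr$concentration)
    paths <- write_precise_csv(df, file.path(out, "trace.csv"))
    write_manifest(out, list(design = "trace", stages = unclass(stages),
                             wall = unclass(wall),
                             constants = unclass(constants),
                             noise = unclass(noise)))
  } else {
    stop_validation("unknown design '", config$design,
                    "' (expected fluorescence, uptake or trace)")
  }
  pef_log(config, "simulate: wrote ", length(paths), " dataset file(s) to ", out)
  invisible(paths)
}

fit_result_to_files <- function(fit, out_dir, units) {
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    std_error = unname(fit$std_errors[names(fit$estimates)]),
                    unit = units[seq_along(fit$estimates)])
  write_precise_csv(tab, file.path(out_dir, "fit_parameters.csv"))
  write_manifest(out_dir, list(
    estimates = as.list(fit$estimates),
    std_errors = as.list(fit$std_errors),
    r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
    n_points = fit$n_points, n_params = fit$n_params,
    converged = fit$converged, flags = as.list(fit$flags)),
    name = "fit_report.json")
}

#' Fit a model to dataset files on disk
#'
#' Reads the CSV dataset(s) written by [run_simulate()] (or any files with
#' the same columns), averages intensities/ratios across replicates at each
#' delay (the designs report means of repeats), runs the matching estimation
#' routine and writes a parameter table with units and standard errors plus
#' a JSON fit report.
#'
#' @param config a validated run configuration with `type`
#'   (`"fluorescence"` or `"uptake"`), `inputs` (file paths; for uptake one
#'   file per field) and `out_dir`; uptake fits also use `N_m`, `N_s`,
#'   `k_a0`, `shared_tau_d`, `fix_k_a0`.
#' @return The `pef_fit` result, invisibly.
#' @export
run_fit <- function(config) {
  config <- resolve_and_record(config, "fit")
  if (config$type == "fluorescence") {
    df <- read_checked_csv(config$inputs[1],
                           c("replicate", "delta_t_s", "intensity_au"))
    mean_i <- tapply(df$intensity_au, df$delta_t_s, mean)
    series <- fluorescence_series(as.numeric(names(mean_i)), as.numeric(mean_i))
    fit <- fit_fluorescence_decay(series)
    fit_result_to_files(fit, config$out_dir, c("a.u.", "a.u.", "s"))
  } else if (config$type == "uptake") {
    if (is.null(config$k_a0) && isTRUE(config$fix_k_a0 %||% TRUE))
      stop_validation("uptake fits with fixed k_a0 require config$k_a0")
    constants <- uptake_constants(N_m = config$N_m %||% 0.5,
                                  N_s = config$N_s %||% 1.0)
    datasets <- lapply(config$inputs, function(p) {
      df <- read_checked_csv(p, c("field_kV_cm", "delta_t_s", "ratio"))
      mean_r <- tapply(df$ratio, df$delta_t_s, mean)
      uptake_dataset(df$field_kV_cm[1], as.numeric(names(mean_r)),
                     pmin(pmax(as.numeric(mean_r), 0), 1))
    })
    fit <- fit_uptake_recovery(datasets, constants,
                               k_a0 = config$k_a0 %||% 7.329e-4,
                               shared_tau_d = config$shared_tau_d %||% TRUE,
                               fix_k_a0 = config$fix_k_a0 %||% TRUE)
    units <- c("s", rep("1/(uM s)", length(fit$estimates) - 1L))
    fit_result_to_files(fit, config$out_dir, units)
  } else {
    stop_validation("unknown fit type '", config$type, "'")
  }
  pef_log(config, "fit: ", config$type, " model, converged = ", fit$converged)
  invisible(fit)
}

#' Calibrate the uptake model from anchors and write the result
#'
#' @param config a validated run configuration; anchor ratios, incubation
#'   time, `tau_d` and the chemical constants default to the study values.
#' @return The calibration list, invisibly.
#' @export
run_calibrate <- function(config) {
  config <- resolve_and_record(config, "calibrate")
  constants <- uptake_constants(N_m = config$N_m %||% 0.5,
                                N_s = config$N_s %||% 1.0)
  anchors <- anchor_set(baseline_ratio = config$baseline_ratio %||% 0.12,
                        delta0_ratio = config$delta0_ratio %||% 0.65,
                        incubation_t = config$incubation_t %||% 180,
                        tau_d = config$tau_d %||% 24)
  cal <- calibrate_from_anchors(anchors, constants)
  tab <- data.frame(parameter = c("k_a0", "A_reference", "tau_d"),
                    value = c(cal$k_a0, cal$A_reference, anchors$tau_d),
                    unit = c("1/(uM s)", "1/(uM s)", "s"))
  write_precise_csv(tab, file.path(config$out_dir, "calibration.csv"))
  write_manifest(config$out_dir,
                 list(anchors = unclass(anchors),
                      constants = unclass(constants),
                      k_a0 = cal$k_a0, A_reference = cal$A_reference),
                 name = "calibration.json")
  pef_log(config, "calibrate: k_a0 = ", signif(cal$k_a0, 6),
          ", A_reference = ", signif(cal$A_reference, 6))
  invisible(cal)
}

#' Run a Monte-Carlo recovery experiment and write its summary
#'
#' Builds the generator truth (calibrated study parameters by default),
#' runs [recovery_experiment()], and writes `recovery_summary.csv` plus a
#' short text report stating the generating parameter values and the
#' recovered means.
#'
#' @param config a validated run configuration with `model`
#'   (`"uptake"` or `"fluorescence"`), `out_dir`, and optional `sigma`,
#'   `n_replicates`, `seed` and generator parameters.
#' @return The summary `data.frame`, invisibly.
#' @export
run_recover <- function(config) {
  config <- resolve_and_record(config, "recover")
  noise <- noise_spec(
    sigma = config$sigma %||% if (config$model == "uptake") 0.03 else 2,
    seed = config$seed %||% 20191014,
    n_replicates = config$n_replicates %||% 100)
  if (config$model == "fluorescence") {
    rc <- list(model = "fluorescence",
               params = fluorescence_params(I0 = config$I0 %||% 100,
                                            I_r = config$I_r %||% 20,
                                            tau_l = config$tau_l %||% 20),
               delta_t_grid = config$delta_t_grid %||% c(10, 30, 90, 180, 360, 600),
               noise = noise)
  } else if (config$model == "uptake") {
    setup <- uptake_study_setup(config)
    rc <- list(model = "uptake", constants = setup$constants,
               wall_by_field = setup$wall_by_field, fields = setup$fields,
               delta_t_grid = setup$delta_t_grid,
               incubation_t = setup$incubation_t, noise = noise)
  } else {
    stop_validation("unknown model '", config$model, "'")
  }
  summary <- recovery_experiment(rc)
  write_precise_csv(summary, file.path(config$out_dir, "recovery_summary.csv"))
  rep_lines <- c(
    sprintf("Parameter recovery report (%s model)", config$model),
    sprintf("replicates: %d, noise sigma: %g, seed: %d",
            noise$n_replicates, noise$sigma, noise$seed),
    "",
    sprintf("%-12s %12s %14s %12s %12s", "parameter", "true",
            "mean_estimate", "bias", "rmse"),
    sprintf("%-12s %12.6g %14.6g %12.3g %12.3g", summary$parameter,
            summary$true, summary$mean_estimate, summary$bias, summary$rmse))
  writeLines(rep_lines, file.path(config$out_dir, "recovery_report.txt"))
  pef_log(config, "recover: ", config$model, " summary written to ",
          config$out_dir)
  invisible(summary)
}
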