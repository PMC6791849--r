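# Synthetic-data generators mirroring the three experimental designs:
# fluorescence decay series, uptake-recovery ratio datasets, and TPP+
# electrode traces. Noiseless outputs equal the closed-form kinetics
# exactly; noise is additive Gaussian on the reported quantity.

#' Generate fluorescence decay series
#'
#' Evaluates the exponential-plus-residual membrane model on a delay grid
#' and adds Gaussian noise. The default grid is the six dye-addition delays
#' of the membrane-resealing design (10-600 s).
#'
#' @param params a [fluorescence_params()] object.
#' @param delta_t_grid dye-addition delays, seconds.
#' @param noise a [noise_spec()]; `sigma` in a.u.
#' @return A list of `noise$n_replicates` [fluorescence_series()] objects.
#'   Deterministic given `noise$seed`; replicate streams are drawn
#'   sequentially from the master seed.
#' @examples
#' g <- generate_fluorescence_series(fluorescence_params(100, 20, 20),
#'                                   noise = noise_spec(sigma = 2, seed = 1))
#' g[[1]]
#' @export
generate_fluorescence_series <- function(params,
                                         delta_t_grid = c(10, 30, 90, 180, 360, 600),
                                         noise = noise_spec()) {
  stopifnot(inherits(params, "fluorescence_params"),
            inherits(noise, "noise_spec"))
  if (!length(delta_t_grid) || any(delta_t_grid < 0))
    stop_validation("'delta_t_grid' must be non-empty and non-negative")
  mu <- fluorescence_intensity(params, delta_t_grid)
  set.seed(noise$seed)
  lapply(seq_len(noise$n_replicates), function(i) {
    fluorescence_series(delta_t_grid,
                        mu + stats::rnorm(length(mu), 0, noise$sigma),
                        replicate_id = sprintf("rep%03d", i))
  })
}

#' Generate uptake-recovery datasets
#'
#' Evaluates the delayed-uptake closed form on the post-pulse delay grid for
#' each field strength, adds Gaussian noise, and clips the resulting ratios
#' to `[0, 1]` (means of physical ratios cannot leave the unit interval).
#' Defaults are the ten delays (5-180 s) and the incubation time (180 s) of
#' the wall-recovery design.
#'
#' @param constants an [uptake_constants()] object.
#' @param wall_by_field a named list of [wall_pore_params()], one per field
#'   (same order as `fields`); a single object is recycled.
#' @param fields field strengths, kV/cm.
#' @param delta_t_grid post-pulse delays, seconds.
#' @param incubation_t incubation time, seconds.
#' @param noise a [noise_spec()]; `sigma` on the ratio scale.
#' @return A list of `noise$n_replicates` replicates; each replicate is a
#'   named list of [uptake_dataset()] objects, one per field.
#' @examples
#' cal <- calibrate_from_anchors(anchor_set(), uptake_constants())
#' g <- generate_uptake_dataset(uptake_constants(), list(cal$wall), 5.85,
#'                              noise = noise_spec(sigma = 0.03, seed = 1))
#' g[[1]][["5.85"]]
#' @export
generate_uptake_dataset <- function(constants, wall_by_field, fields,
                                    delta_t_grid = c(5, 10, 20, 30, 40, 50, 60, 80, 120, 180),
                                    incubation_t = 180,
                                    noise = noise_spec()) {
  stopifnot(inherits(constants, "uptake_constants"),
            inherits(noise, "noise_spec"))
  if (inherits(wall_by_field, "wall_pore_params"))
    wall_by_field <- list(wall_by_field)
  if (length(wall_by_field) == 1L)
    wall_by_field <- rep(wall_by_field, length(fields))
  if (length(wall_by_field) != length(fields))
    stop_validation("'wall_by_field' must supply one wall_pore_params per field")
  if (!length(delta_t_grid) || any(delta_t_grid < 0))
    stop_validation("'delta_t_grid' must be non-empty and non-negative")
  f_lab <- formatC(fields, format = "g")
  mu <- lapply(seq_along(fields), function(i)
    uptake_with_delay(constants, wall_by_field[[i]], incubation_t, delta_t_grid))
  set.seed(noise$seed)
  lapply(seq_len(noise$n_replicates), function(r) {
    out <- lapply(seq_along(fields), function(i) {
      y <- mu[[i]] + stats::rnorm(length(delta_t_grid), 0, noise$sigma)
      uptake_dataset(fields[i], delta_t_grid, pmin(pmax(y, 0), 1), incubation_t)
    })
    stats::setNames(out, f_lab)
  })
}

#' Generate a three-stage TPP+ electrode trace
#'
#' Simulates the supernatant TPP+ concentration seen by the ion-selective
#' electrode after yeast is injected into the probe solution: a fast
#' adsorption drop (stage I), a delay plateau (stage II, absent after PEF),
#' and the slow absorption described by the closed-form uptake model
#' (stage III). The initial concentration is `N_s + stage1_amplitude`, so
#' the plateau sits at the slow-stage pool level `N_s`.
#'
#' @param constants an [uptake_constants()] object.
#' @param wall a [wall_pore_params()] object governing stage III.
#' @param stages a [trace_stage_spec()].
#' @param t_grid time grid starting at 0, seconds, increasing.
#' @param noise a [noise_spec()]; `sigma` in uM.
#' @return A `data.frame` with columns `time` (s) and `concentration` (uM).
#' @examples
#' tr <- generate_electrode_trace(uptake_constants(),
#'                                wall_pore_params(7.329e-4, 0, 24),
#'                                trace_stage_spec(), t_grid = seq(0, 600, 5))
#' head(tr)
#' @export
generate_electrode_trace <- function(constants, wall,
                                     stages = trace_stage_spec(),
                                     t_grid = seq(0, 600, by = 1),
                                     noise = noise_spec()) {
  stopifnot(inherits(constants, "uptake_constants"),
            inherits(wall, "wall_pore_params"),
            inherits(stages, "trace_stage_spec"),
            inherits(noise, "noise_spec"))
  if (!length(t_grid) || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop_validation("'t_grid' must start at 0 and be strictly increasing")
  c0 <- constants$N_s + stages$stage1_amplitude
  drop1 <- stages$stage1_amplitude * (1 - exp(-t_grid / stages$stage1_tau))
  t_abs <- pmax(t_grid - stages$stage2_duration, 0)
  absorbed <- uptake_closed_form(constants, wall, t_abs)
  conc <- c0 - drop1 - absorbed
  if (noise$sigma > 0) {
    set.seed(noise$seed)
    conc <- conc + stats::rnorm(length(conc), 0, noise$sigma)
  }
  data.frame(time = t_grid, concentration = conc)
}
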