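# Closed-form and numerical kinetics of post-pulse TPP+ uptake and of the
# membrane fluorescence decay.
#
# The uptake model is the pseudo-second-order law
#   dN/dt = k_a(t) (N_m - N)(N_s - N),  N(0) = 0,
# with an absorption coefficient that relaxes back to its baseline as the
# PEF-induced wall pores reseal:
#   k_a(t) = k_a0 + A exp(-delta_t/tau_d) exp(-t/tau_d),
# where delta_t is the delay between the pulse and TPP+ addition. Because
# k_a depends on time only, the ODE separates and has the closed form
#   N(t) = N_m (1 - S) / (1 - R S),  R = N_m/N_s,
#   S    = exp((N_m - N_s) K(t)),    K(t) = Integral of k_a dt.

# relative tolerance below which N_m and N_s are treated as equal roots
EQUAL_ROOTS_TOL <- 1e-9

#' PEF pore-term amplitude from field-response parameters
#'
#' Evaluates the parametric field dependence of the pore-term amplitude,
#' `A = b (E_p - E_th_p)^2 f^2 [1 - exp(-t_p/t_ch)]^2` for fields above the
#' permeabilization threshold and exactly 0 at or below it (no excess pores
#' are created below threshold). The saturating (negative-exponent) membrane
#' charging factor is used; see the methods vignette for the rationale.
#'
#' @param field_response a [field_response_params()] object.
#' @param pulse a [pulse_spec()] object (`t_p` and `t_ch` are both in
#'   microseconds, so their ratio is dimensionless).
#' @return Pore-term amplitude `A` in 1/(uM s); non-decreasing in both
#'   `E_p` and `t_p`.
#' @examples
#' fr <- field_response_params(b = 0.01, E_th_p = 2.0, t_ch = 1)
#' pef_amplitude(fr, pulse_spec(E_p = 4.0, t_p = 1))
#' @export
pef_amplitude <- function(field_response, pulse) {
  stopifnot(inherits(field_response, "field_response_params"),
            inherits(pulse, "pulse_spec"))
  over <- pulse$E_p - field_response$E_th_p
  if (over <= 0) return(0)
  charging <- 1 - exp(-pulse$t_p / field_response$t_ch)
  field_response$b * over^2 * field_response$f^2 * charging^2
}

#' Transient pore excess at time t after the pulse
#'
#' The PEF-created excess of wall pores decays exponentially,
#' `A exp(-t/tau_d)`, as the wall reseals.
#'
#' @param A initial pore-term amplitude, 1/(uM s).
#' @param tau_d pore lifetime, seconds (> 0).
#' @param t time since the pulse, seconds (vectorized, >= 0).
#' @return The surviving pore contribution to the absorption coefficient,
#'   1/(uM s); strictly decreasing in `t` when `A > 0`.
#' @examples
#' pore_excess(A = 0.0493, tau_d = 24, t = c(0, 24, 48))
#' @export
pore_excess <- function(A, tau_d, t) {
  check_scalar(A, "A", lower = 0)
  check_scalar(tau_d, "tau_d", lower = 0, strict = TRUE)
  if (any(!is.finite(t) | t < 0)) stop_validation("'t' must be non-negative")
  A * exp(-t / tau_d)
}

#' Time-dependent absorption coefficient k_a(t)
#'
#' Baseline plus decaying pore excess: `k_a0 + A exp(-t/tau_d)`. Always at
#' least `k_a0`, and converging back to `k_a0` as the wall reseals.
#'
#' @param wall a [wall_pore_params()] object.
#' @param t time since the pulse, seconds (vectorized, >= 0).
#' @return `k_a(t)` in 1/(uM s).
#' @examples
#' w <- wall_pore_params(k_a0 = 7.329e-4, A = 0.0493, tau_d = 24)
#' absorption_rate(w, t = c(0, 24, 1e6))
#' @export
absorption_rate <- function(wall, t) {
  stopifnot(inherits(wall, "wall_pore_params"))
  wall$k_a0 + pore_excess(wall$A, wall$tau_d, t)
}

# Accumulated rate integral K(t) = Integral_0^t k_a(u; delta_t) du, 1/uM.
rate_integral <- function(wall, t, delta_t = 0) {
  wall$k_a0 * t +
    wall$A * wall$tau_d * exp(-delta_t / wall$tau_d) * (1 - exp(-t / wall$tau_d))
}

# Map the accumulated rate integral K to the absorbed amount N (uM),
# handling the equal-roots degeneracy N_m ~= N_s continuously.
uptake_from_integral <- function(constants, K) {
  N_m <- constants$N_m
  N_s <- constants$N_s
  if (abs(N_m - N_s) < EQUAL_ROOTS_TOL * N_s) {
    # limit of the two-root solution: dN/dt = k_a (N_m - N)^2
    return(N_m - N_m / (1 + N_m * K))
  }
  if (N_m > N_s)
    stop_validation("uptake solution requires N_m < N_s (or equal within tolerance)")
  S <- exp((N_m - N_s) * K)
  N_m * (1 - S) / (1 - (N_m / N_s) * S)
}

#' Closed-form absorbed amount N(t) with no post-pulse delay
#'
#' Solves the pseudo-second-order uptake law with the resealing absorption
#' coefficient in closed form:
#' `K(t) = k_a0 t + A tau_d (1 - exp(-t/tau_d))`,
#' `S = exp((N_m - N_s) K)`, `N = N_m (1 - S)/(1 - R S)` with `R = N_m/N_s`.
#'
#' @param constants an [uptake_constants()] object.
#' @param wall a [wall_pore_params()] object.
#' @param t incubation time since TPP+ addition, seconds (vectorized, >= 0).
#' @return Absorbed amount `N` in uM: 0 at `t = 0`, strictly increasing when
#'   `k_a0 > 0`, bounded above by `N_m`.
#' @examples
#' ct <- uptake_constants(N_m = 0.5, N_s = 1.0)
#' w  <- wall_pore_params(k_a0 = 7.329e-4, A = 0, tau_d = 24)
#' uptake_closed_form(ct, w, t = 180) / ct$N_m   # untreated 3-min level
#' @export
uptake_closed_form <- function(constants, wall, t) {
  stopifnot(inherits(constants, "uptake_constants"),
            inherits(wall, "wall_pore_params"))
  if (any(!is.finite(t) | t < 0)) stop_validation("'t' must be non-negative")
  uptake_from_integral(constants, rate_integral(wall, t, delta_t = 0))
}

#' Absorbed fraction N/N_m when TPP+ is added a delay after the pulse
#'
#' When the probe ion is added `delta_t` seconds after the pulse the excess
#' pores have already decayed by `exp(-delta_t/tau_d)`, giving
#' `S_dt = exp((N_m - N_s)[k_a0 t + A tau_d e^(-delta_t/tau_d)(1 - e^(-t/tau_d))])`
#' and the absorbed fraction `(1 - S_dt)/(1 - R S_dt)`.
#'
#' @param constants an [uptake_constants()] object.
#' @param wall a [wall_pore_params()] object.
#' @param t incubation time after TPP+ addition, seconds.
#' @param delta_t post-pulse delay before TPP+ addition, seconds
#'   (vectorized, >= 0).
#' @return Absorbed fraction `N/N_m` in (0, 1): non-increasing in `delta_t`,
#'   equal to `uptake_closed_form()/N_m` at `delta_t = 0`, and converging to
#'   [baseline_uptake()] as `delta_t` grows (full wall recovery).
#' @examples
#' ct <- uptake_constants()
#' w  <- wall_pore_params(k_a0 = 7.329e-4, A = 0.049262, tau_d = 24)
#' uptake_with_delay(ct, w, t = 180, delta_t = c(0, 48, 600))
#' @export
uptake_with_delay <- function(constants, wall, t, delta_t) {
  stopifnot(inherits(constants, "uptake_constants"),
            inherits(wall, "wall_pore_params"))
  if (any(!is.finite(t) | t < 0)) stop_validation("'t' must be non-negative")
  if (any(!is.finite(delta_t) | delta_t < 0))
    stop_validation("'delta_t' must be non-negative")
  K <- rate_integral(wall, t, delta_t = delta_t)
  uptake_from_integral(constants, K) / constants$N_m
}

#' Untreated baseline absorbed fraction N0/N_m
#'
#' The fully recovered (or never pulsed) wall absorbs through the baseline
#' coefficient only: `S0 = exp((N_m - N_s) k_a0 t)`,
#' `N0/N_m = (1 - S0)/(1 - R S0)`. Identical to [uptake_with_delay()] with
#' `A = 0`.
#'
#' @param constants an [uptake_constants()] object.
#' @param k_a0 baseline absorption coefficient, 1/(uM s).
#' @param t incubation time, seconds (vectorized, >= 0).
#' @return Baseline absorbed fraction `N0/N_m`.
#' @examples
#' baseline_uptake(uptake_constants(), k_a0 = 7.329e-4, t = 180)
#' @export
baseline_uptake <- function(constants, k_a0, t) {
  stopifnot(inherits(constants, "uptake_constants"))
  check_scalar(k_a0, "k_a0", lower = 0)
  if (any(!is.finite(t) | t < 0)) stop_validation("'t' must be non-negative")
  wall <- wall_pore_params(k_a0 = k_a0, A = 0, tau_d = 1)
  uptake_from_integral(constants, rate_integral(wall, t)) / constants$N_m
}

#' Fluorescence intensity a delay after the pulse
#'
#' `I(delta_t) = I0 exp(-delta_t/tau_l) + I_r`: the lipidic membrane pores
#' reseal exponentially, leaving the residual intensity `I_r`.
#'
#' @param params a [fluorescence_params()] object.
#' @param delta_t delay between the pulse and dye addition, seconds
#'   (vectorized, >= 0).
#' @return Intensity in arbitrary units; strictly decreasing for `I0 > 0`
#'   with infimum `I_r`.
#' @examples
#' fluorescence_intensity(fluorescence_params(100, 20, 20), delta_t = c(0, 20, 100))
#' @export
fluorescence_intensity <- function(params, delta_t) {
  stopifnot(inherits(params, "fluorescence_params"))
  if (any(!is.finite(delta_t) | delta_t < 0))
    stop_validation("'delta_t' must be non-negative")
  params$I0 * exp(-delta_t / params$tau_l) + params$I_r
}

#' Numerical (RK4) integration of the uptake ODE
#'
#' Integrates `dN/dt = k_a(t) (N_m - N)(N_s - N)` with
#' `k_a(t) = k_a0 + A exp(-delta_t/tau_d) exp(-t/tau_d)` using a fixed-step
#' classical 4th-order Runge-Kutta scheme. The step is at most
#' `0.01 min(tau_d, 1/(k_a_max N_s))`, so the result is deterministic and
#' reproducible bit-for-bit given the inputs. This is the independent
#' numerical oracle for the closed-form solution: the two agree to a
#' relative (to `N_m`) deviation of 1e-6 over the grid.
#'
#' @param constants an [uptake_constants()] object.
#' @param wall a [wall_pore_params()] object.
#' @param delta_t post-pulse delay, seconds.
#' @param t_grid strictly increasing time grid starting at 0, seconds.
#' @return Numeric vector of absorbed amounts `N` (uM) at `t_grid`.
#' @examples
#' ct <- uptake_constants()
#' w  <- wall_pore_params(k_a0 = 7.329e-4, A = 0.049262, tau_d = 24)
#' integrate_uptake_ode(ct, w, delta_t = 0, t_grid = c(0, 60, 180))
#' @export
integrate_uptake_ode <- function(constants, wall, delta_t = 0, t_grid) {
  stopifnot(inherits(constants, "uptake_constants"),
            inherits(wall, "wall_pore_params"))
  check_scalar(delta_t, "delta_t", lower = 0)
  if (length(t_grid) < 1L || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop_validation("'t_grid' must start at 0 and be strictly increasing")
  k_a_max <- wall$k_a0 + wall$A * exp(-delta_t / wall$tau_d)
  h <- 0.01 * min(wall$tau_d,
                  if (k_a_max > 0) 1 / (k_a_max * constants$N_s) else Inf)
  h <- min(h, max(t_grid) / 10)
  times <- sort(unique(c(seq(0, max(t_grid), by = h), t_grid)))
  deriv <- function(t, y, parms) {
    k_a <- wall$k_a0 + wall$A * exp(-delta_t / wall$tau_d) * exp(-t / wall$tau_d)
    list(k_a * (constants$N_m - y[1]) * (constants$N_s - y[1]))
  }
  sol <- deSolve::ode(y = c(N = 0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  sol[match(t_grid, sol[, "time"]), "N"]
}
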