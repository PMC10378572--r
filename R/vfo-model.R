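#' Vocal-fold oscillator parameters
#'
#' Parameters of the asymmetric one-mass body-cover model of the vocal folds,
#' a pair of coupled Van der Pol oscillators. `alpha` is the glottal-pressure
#' coupling coefficient (the only energy input to the oscillation), `beta`
#' lumps mass, spring and damping coefficients, and `delta` is the asymmetry
#' coefficient that detunes the restoring forces of the left and right folds.
#' For a normal adult male voice the clinical reference values are
#' approximately `alpha = 0.5`, `beta = 0.32`, `delta = 0`.
#'
#' The model is invariant under simultaneously negating `delta` and swapping
#' the two folds, so `delta >= 0` is adopted as a convention; negative values
#' are accepted (they are meaningful, merely relabelled folds) but fitting
#' routines report the non-negative representative.
#'
#' @param alpha glottal pressure coupling coefficient (dimensionless)
#' @param beta combined mass/spring/damping coefficient, must be > 0
#' @param delta asymmetry coefficient (dimensionless)
#' @return an object of class `vfo_params`
#' @examples
#' vfo_params(0.5, 0.32, 0)
#' @export
vfo_params <- function(alpha = 0.5, beta = 0.32, delta = 0) {
  stopifnot(length(alpha) == 1, length(beta) == 1, length(delta) == 1)
  stop_if_not_finite(c(alpha, beta, delta), "vfo_params")
  if (beta <= 0) stop("beta must be > 0 (damping)", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, delta = delta),
            class = "vfo_params")
}

#' @export
print.vfo_params <- function(x, ...) {
  cat(sprintf("vocal-fold oscillator parameters: alpha = %.4g, beta = %.4g, delta = %.4g\n",
              x$alpha, x$beta, x$delta))
  invisible(x)
}

#' Initial conditions for the fold oscillator
#'
#' Quiescent positions `xi_r0`, `xi_l0` and initial velocities of the two
#' folds. The folds are assumed at rest before phonation onset, so the
#' velocities default to zero. Note that the all-zero state is an exact
#' equilibrium of the model; simulations intended to reach the limit cycle
#' should start from a small perturbation (the default).
#'
#' @param xi_r0,xi_l0 initial displacements (dimensionless)
#' @param v_r0,v_l0 initial velocities (dimensionless), default 0
#' @return an object of class `vfo_ics`
#' @export
vfo_ics <- function(xi_r0 = 0.01, xi_l0 = 0.01, v_r0 = 0, v_l0 = 0) {
  stop_if_not_finite(c(xi_r0, xi_l0, v_r0, v_l0), "vfo_ics")
  structure(list(xi_r0 = xi_r0, xi_l0 = xi_l0, v_r0 = v_r0, v_l0 = v_l0),
            class = "vfo_ics")
}

as_state <- function(ics) c(ics$xi_r0, ics$v_r0, ics$xi_l0, ics$v_l0)

#' Glottal geometry for the flow computation
#'
#' Static geometry converting fold displacement to glottal volume velocity:
#' `u0(t) = c_tilde * d * (2*xi0 + xi_l(t) + xi_r(t))`. Defaults are the
#' typical adult values: half glottal width at rest `xi0` = 0.1 cm, fold
#' length `d` = 1.75 cm, mid-fold air particle velocity `c_tilde` = 5000 cm/s.
#'
#' @param xi0 half glottal width at rest (cm)
#' @param d vocal-fold length (cm)
#' @param c_tilde air particle velocity at the fold midpoint (cm/s)
#' @return an object of class `fold_geometry`
#' @export
fold_geometry <- function(xi0 = 0.1, d = 1.75, c_tilde = 5000) {
  stopifnot(xi0 > 0, d > 0, c_tilde > 0)
  structure(list(xi0 = xi0, d = d, c_tilde = c_tilde),
            class = "fold_geometry")
}

#' Model-time to physical-time mapping
#'
#' The oscillator evolves in dimensionless model time in which the natural
#' (uncoupled, symmetric) frequency is 1 rad per unit. A fundamental
#' frequency `f0` maps model time to seconds as
#' `t_seconds = t_model / (2 * pi * f0)`, so one oscillation period of the
#' symmetric model spans roughly `1/f0` seconds.
#'
#' @param f0 fundamental frequency in Hz
#' @param mode `"fixed"` or `"estimated-from-audio"` (bookkeeping flag used
#'   by fitting front-ends)
#' @return an object of class `time_scale`
#' @export
time_scale <- function(f0 = 150, mode = c("fixed", "estimated-from-audio")) {
  stopifnot(is.finite(f0), f0 > 0)
  mode <- match.arg(mode)
  structure(list(f0 = f0, mode = mode), class = "time_scale")
}

model_to_seconds <- function(t_model, ts) t_model / (2 * pi * ts$f0)
seconds_to_model <- function(t_sec, ts) t_sec * 2 * pi * ts$f0

#' Right-hand side of the asymmetric fold oscillator
#'
#' Time derivatives of the state `(xi_r, v_r, xi_l, v_l)` under the coupled
#' Van der Pol system
#' \deqn{\ddot\xi_r + \beta(1+\xi_r^2)\dot\xi_r + \xi_r - \frac{\Delta}{2}\xi_r
#'   = \alpha(\dot\xi_r + \dot\xi_l)}
#' \deqn{\ddot\xi_l + \beta(1+\xi_l^2)\dot\xi_l + \xi_l + \frac{\Delta}{2}\xi_l
#'   = \alpha(\dot\xi_r + \dot\xi_l)}
#' The damping term is dissipative for all displacements; the only energy
#' input is the pressure coupling through `alpha`, so self-sustained
#' oscillation requires `2*alpha > beta` (symmetric case).
#'
#' @param state numeric length-4 vector `(xi_r, v_r, xi_l, v_l)`
#' @param params a [vfo_params] object
#' @return numeric length-4 vector of derivatives
#' @export
vdp_rhs <- function(state, params) {
  if (!all(is.finite(state))) stop("invalid state: non-finite", call. = FALSE)
  xi_r <- state[1]; v_r <- state[2]; xi_l <- state[3]; v_l <- state[4]
  couple <- params$alpha * (v_r + v_l)
  c(v_r,
    -params$beta * (1 + xi_r^2) * v_r - xi_r + (params$delta / 2) * xi_r + couple,
    v_l,
    -params$beta * (1 + xi_l^2) * v_l - xi_l - (params$delta / 2) * xi_l + couple)
}

# deSolve wrapper
vdp_desolve <- function(t, y, parms) list(vdp_rhs(y, parms))

#' Simulate the fold oscillator
#'
#' Integrates the asymmetric oscillator with an adaptive explicit Runge-Kutta
#' scheme (Dormand-Prince 4/5, `rtol` 1e-8, `atol` 1e-10) and returns the
#' solution sampled on a uniform grid. The system is non-stiff in the
#' physiological parameter ranges.
#'
#' @param params a [vfo_params] object
#' @param ics a [vfo_ics] object; defaults to a small symmetric perturbation
#' @param duration simulation length in model-time units
#' @param dt output sampling interval in model-time units
#' @param timescale a [time_scale] attached to the result for unit conversion
#' @param rtol,atol solver tolerances
#' @return a `vfo_trajectory`: data frame with columns `t`, `xi_r`, `v_r`,
#'   `xi_l`, `v_l` and attribute `timescale`
#' @examples
#' traj <- simulate_vfo(vfo_params(0.5, 0.32, 0), duration = 100)
#' range(traj$xi_r)
#' @export
simulate_vfo <- function(params, ics = vfo_ics(), duration = 2000, dt = 0.02,
                         timescale = time_scale(), rtol = 1e-8, atol = 1e-10) {
  stopifnot(duration > 0, dt > 0)
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(as_state(ics), times, vdp_desolve, params,
                      method = "ode45", rtol = rtol, atol = atol)
  if (!all(is.finite(sol))) {
    last_ok <- max(which(apply(is.finite(sol), 1, all)))
    stop(sprintf("integration failure: non-finite state after t = %.6g",
                 sol[last_ok, 1]), call. = FALSE)
  }
  new_vfo_trajectory(sol[, 1], sol[, 2], sol[, 3], sol[, 4], sol[, 5],
                     timescale)
}

new_vfo_trajectory <- function(t, xi_r, v_r, xi_l, v_l, timescale = time_scale()) {
  out <- data.frame(t = t, xi_r = xi_r, v_r = v_r, xi_l = xi_l, v_l = v_l)
  attr(out, "timescale") <- timescale
  class(out) <- c("vfo_trajectory", "data.frame")
  out
}

#' Glottal volume velocity from a fold trajectory
#'
#' Pointwise flow conversion `u0(t) = c_tilde * d * (2*xi0 + xi_l + xi_r)`.
#' Displacements from the dimensionless model are used directly as cm.
#'
#' @param traj a `vfo_trajectory`
#' @param geom a [fold_geometry]
#' @return a `glottal_flow`: data frame with columns `t` (model time) and
#'   `u0` (cm^3/s), carrying the trajectory's `timescale`
#' @export
glottal_flow <- function(traj, geom = fold_geometry()) {
  stopifnot(nrow(traj) > 0)
  u0 <- geom$c_tilde * geom$d * (2 * geom$xi0 + traj$xi_l + traj$xi_r)
  out <- data.frame(t = traj$t, u0 = u0)
  attr(out, "timescale") <- attr(traj, "timescale")
  class(out) <- c("glottal_flow", "data.frame")
  out
}
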