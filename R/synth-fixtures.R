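#' Synthetic glottal-flow case with known ground truth
#'
#' Simulates the fold oscillator at known parameters and converts to
#' glottal flow, optionally adding seeded Gaussian noise scaled to the flow
#' oscillation amplitude. Regenerating with the same arguments (including
#' `seed`) reproduces the series bitwise.
#'
#' @param truth_params [vfo_params] ground truth
#' @param ics [vfo_ics] (also the fitting assumption in the backward mode)
#' @param geom [fold_geometry]
#' @param f0 fundamental frequency (Hz) for the attached [time_scale]
#' @param duration,dt model-time span and sampling of the flow
#' @param noise_sd additive Gaussian noise, relative to the standard
#'   deviation of the noiseless flow; 0 disables noise
#' @param seed RNG seed (required when `noise_sd > 0`)
#' @return a `synthetic_case` list: `truth_params`, `ics`, `geom`, `f0`,
#'   `noise_sd`, `seed`, `trajectory`, `ug` (a `glottal_flow`), and
#'   `oscillating` (FALSE when the truth regime decays to rest)
#' @export
synth_glottal_case <- function(truth_params, ics = vfo_ics(),
                               geom = fold_geometry(), f0 = 150,
                               duration = 50, dt = 0.02,
                               noise_sd = 0, seed = 1L) {
  ts <- time_scale(f0)
  traj <- simulate_vfo(truth_params, ics, duration, dt, timescale = ts)
  flow <- glottal_flow(traj, geom)
  tail_amp <- diff(range(traj$xi_r[traj$t >= 0.75 * duration]))
  head_amp <- diff(range(traj$xi_r[traj$t <= 0.25 * duration]))
  # decaying regimes shrink toward the end of the run; sustained ones grow
  # to (or stay on) a finite-amplitude cycle. Near-threshold decay can be
  # slow, so give the run enough length for the trend to show.
  oscillating <- tail_amp > 1e-3 && tail_amp >= 0.8 * head_amp
  if (!oscillating) {
    warning("truth regime is not self-oscillating (decaying amplitude)",
            call. = FALSE)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    flow$u0 <- flow$u0 +
      stats::rnorm(nrow(flow), 0, noise_sd * stats::sd(flow$u0))
  }
  structure(list(truth_params = truth_params, ics = ics, geom = geom,
                 f0 = f0, noise_sd = noise_sd, seed = seed,
                 trajectory = traj, ug = flow, oscillating = oscillating),
            class = "synthetic_case")
}

#' Synthetic recorded-voice case with known ground truth
#'
#' Extends [synth_glottal_case] through the vocal tract: the true glottal
#' flow is propagated forward with a known source profile, giving the lip
#' velocity `um` and the corresponding lip pressure `pm` (the inverse of
#' the pressure-to-velocity conversion). Noise, when requested, is added to
#' the standardized lip signal.
#'
#' @inheritParams synth_glottal_case
#' @param truth_profile a [vt_profile] on the `cfg` grid, `NULL` for a
#'   rigid tract, or `"smooth"` for a built-in smooth space-time profile in
#'   the range of the time-reversal operator (band-limited in time, hence
#'   observable at the lips after standardization)
#' @param cfg [vt_config]
#' @param duration_s physical signal length in seconds
#' @return a `synthetic_case` list, adding `cfg`, `truth_profile`,
#'   `t_phys`, `um`, `pm`, and `u0` (the true glottal flow on the solver
#'   grid)
#' @export
synth_speech_case <- function(truth_params, truth_profile = NULL,
                              cfg = vt_config(), ics = vfo_ics(),
                              geom = fold_geometry(), f0 = 150,
                              duration_s = 0.05, noise_sd = 0, seed = 1L) {
  ts <- time_scale(f0)
  nt <- floor(duration_s / cfg$dt)
  t_phys <- (0:(nt - 1)) * cfg$dt
  t_model <- seconds_to_model(t_phys, ts)
  sol <- deSolve::ode(as_state(ics), t_model, vdp_desolve, truth_params,
                      method = "ode45", rtol = 1e-8, atol = 1e-10)
  traj <- new_vfo_trajectory(sol[, 1], sol[, 2], sol[, 3], sol[, 4],
                             sol[, 5], ts)
  u0 <- geom$c_tilde * geom$d * (2 * geom$xi0 + traj$xi_l + traj$xi_r)
  if (identical(truth_profile, "smooth")) {
    pulse <- exp(-((t_phys - duration_s / 2) / (duration_s / 8))^2) *
      sin(2 * pi * 300 * t_phys)
    zf <- propagate_time_reversed(pulse, NULL, cfg)$z
    truth_profile <- vt_profile(zf * 3e10 / max(abs(zf)), cfg)
  }
  um <- propagate_forward(u0, truth_profile, cfg)$uL
  if (noise_sd > 0) {
    set.seed(seed)
    um <- um + stats::rnorm(nt, 0, noise_sd * stats::sd(um))
  }
  pm <- velocity_to_pressure(um, cfg)
  structure(list(truth_params = truth_params, ics = ics, geom = geom,
                 f0 = f0, noise_sd = noise_sd, seed = seed, cfg = cfg,
                 truth_profile = truth_profile, trajectory = traj,
                 t_phys = t_phys, u0 = u0, um = um, pm = pm),
            class = "synthetic_case")
}

#' Parameter presets for the pathology regimes
#'
#' Reference parameter points of the bifurcation-diagram regions used for
#' pathology interpretation (`beta` fixed at the clinical reference 0.32).
#'
#' @param preset one of `"normal"`, `"neoplasm"`, `"phonotrauma"`, `"palsy"`
#' @return a [vfo_params]
#' @export
regime_preset <- function(preset = c("normal", "neoplasm", "phonotrauma",
                                     "palsy")) {
  switch(match.arg(preset),
         normal = vfo_params(0.5, 0.32, 0),
         neoplasm = vfo_params(0.35, 0.32, 0.6),
         phonotrauma = vfo_params(0.3, 0.32, 0.6),
         palsy = vfo_params(0.4, 0.32, 0.85))
}
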