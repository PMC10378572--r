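#' Residual between predicted and measured lip flows
#'
#' Both series are standardized to zero mean and unit variance before
#' differencing (the absolute gain of a recorded signal is unknown:
#' microphone distance and transmission loss are not modelled). Returns both
#' sign conventions: `r` `= um - uL` (drives the time-reversed propagation)
#' and `R = uL - um` (enters the parameter adjoint), together with the
#' trapezoid loss `F = integral R^2 dt`.
#'
#' @param uL predicted lip volume-velocity series
#' @param um measured lip volume-velocity series (same grid)
#' @param dt sample interval (s), used only for the loss quadrature
#' @param normalize standardize both series first (default `TRUE`)
#' @return list with `r`, `R`, `F`
#' @export
lip_residual <- function(uL, um, dt = 1, normalize = TRUE) {
  if (length(uL) != length(um)) {
    stop("uL and um must share a grid; resample first", call. = FALSE)
  }
  if (normalize) { uL <- standardize(uL); um <- standardize(um) }
  R <- uL - um
  t <- seq_along(R) * dt
  list(r = -R, R = R, F = trapz(t, R^2))
}

#' Backproject a lip residual to the glottis
#'
#' Maps a residual series observed at the lips to its sensitivity at the
#' glottal boundary: the exact discrete transpose of the linear propagation
#' map from glottal Dirichlet data to the lip trace. Because the solver
#' starts from rest with time-invariant coefficients, this transpose is
#' computed by time-reversing the residual, running the same forward solver
#' on a rigid tube, and time-reversing the lip trace of the result; it
#' therefore satisfies the discrete adjoint identity
#' `<forward(a), b> == <a, backproject(b)>` to machine precision. The
#' propagation operator is affine in the glottal data, so the source
#' profile does not enter the sensitivity.
#'
#' @param R residual series at the lip
#' @param profile accepted for interface symmetry; unused (see above)
#' @param cfg a [vt_config]
#' @return list with `Rg`, the glottal sensitivity series
#' @export
backproject_residual <- function(R, profile = NULL, cfg = vt_config()) {
  list(Rg = wave_transpose_lip_to_glottis(R, cfg))
}

#' Adjoint states for a lip residual
#'
#' As [solve_adjoint_glottal], but the forcing is the backprojected lip
#' residual `Rg` (the lip misfit mapped to the glottis through the vocal
#' tract): the costate equations are identical with `R` replaced by `Rg`.
#'
#' @param traj forward `vfo_trajectory`
#' @param params [vfo_params] of the forward solve
#' @param Rg backprojected residual on the trajectory grid (the `Rg` element
#'   of [backproject_residual], or a bare numeric vector)
#' @param geom [fold_geometry]
#' @param adjoint_form see [solve_adjoint_glottal]
#' @return an `adjoint_trajectory`
#' @export
solve_adjoint_lip <- function(traj, params, Rg, geom = fold_geometry(),
                              adjoint_form = c("variational", "algebraic")) {
  if (is.list(Rg)) Rg <- Rg$Rg
  solve_adjoint(traj, params, Rg, geom, match.arg(adjoint_form))
}

#' Joint estimation of oscillator parameters and tract profile (ADLES-VFT)
#'
#' Forward-backward analysis-by-synthesis from a recorded voice (lip
#' pressure) signal. Each outer iteration: (1) integrate the fold oscillator
#' and convert to glottal flow; (2) propagate it through the vocal tract;
#' (3) form the standardized lip residual; (4) propagate the residual
#' backward by time reversal and take a line-searched descent step on the
#' source profile `f(x,t)`; (5) backproject the residual to the glottis,
#' solve the fold adjoint, and update `(alpha, delta)` (and optionally
#' `beta`) by gradient descent. The loss is the integrated squared error
#' between the standardized predicted and measured lip flows.
#'
#' `beta` is held at its initialization by default: after standardization
#' the loss carries no amplitude information, which leaves `beta` weakly
#' identifiable and lets it wander (dragging `alpha` and `delta` with it);
#' set `fit_beta = TRUE` for the full three-parameter descent.
#'
#' @param pm measured pressure series: an `audio_signal`, or a numeric
#'   vector with `fs` supplied
#' @param fs sample rate of `pm` in Hz (ignored for `audio_signal` input)
#' @param geom [fold_geometry]
#' @param cfg [vt_config]; its `dt` is the solver grid the signal is
#'   resampled onto
#' @param opt [optimizer_config]
#' @param timescale a [time_scale], or `NULL` to estimate the fundamental
#'   frequency from `pm` by autocorrelation
#' @param segment analysed segment length in seconds (taken centered),
#'   default 0.2
#' @param fit_beta also descend on `beta`? default `FALSE`
#' @param ics [vfo_ics] for the forward solves
#' @param iota0 initial profile step; rescaled automatically on the first
#'   iteration and adapted by backtracking thereafter
#' @param profile_updates profile descent steps per outer iteration
#'   (default 1; 0 freezes the profile)
#' @return an `adles_vft_fit`: `params`, `profile` ([vt_profile]),
#'   `loss_history`, `u0`, `uL`, `um` (standardized), `t_phys`, `t_model`,
#'   `timescale`, `converged`, `n_iter`
#' @export
fit_adles_vft <- function(pm, fs = NULL, geom = fold_geometry(),
                          cfg = vt_config(), opt = optimizer_config(),
                          timescale = NULL, segment = 0.2,
                          fit_beta = FALSE, ics = vfo_ics(),
                          iota0 = NULL, profile_updates = 1L) {
  if (inherits(pm, "audio_signal")) { fs <- pm$fs; pm <- pm$samples }
  if (is.null(fs)) stop("supply fs for a bare numeric pm", call. = FALSE)
  stop_if_not_finite(pm, "pm")

  um_raw <- pressure_to_velocity(pm, cfg)
  # centered segment, resampled onto the solver grid
  dur_in <- length(um_raw) / fs
  seg <- min(segment, dur_in)
  t_in <- (seq_along(um_raw) - 1) / fs
  t0 <- (dur_in - seg) / 2
  nt <- max(16L, floor(seg / cfg$dt))
  t_phys <- (0:(nt - 1)) * cfg$dt
  um <- stats::approx(t_in, um_raw, xout = t0 + t_phys, rule = 2)$y
  umz <- standardize(um)

  if (is.null(timescale)) {
    f0 <- estimate_f0(audio_signal(umz, 1 / cfg$dt))
    timescale <- time_scale(f0, "estimated-from-audio")
  }
  t_model <- seconds_to_model(t_phys, timescale)
  w <- trapz_weights(t_phys)
  wm <- trapz_weights(t_model)

  fmat <- matrix(0, cfg$nx + 1, nt)   # profile initialized to a rigid tube
  iota <- iota0
  p <- c(opt$init_params$alpha, opt$init_params$beta, opt$init_params$delta)
  fit_mask <- c(TRUE, fit_beta, TRUE)
  step <- rep(opt$step_scale, 3)
  gprev <- c(0, 0, 0)
  loss_history <- numeric(0)
  best <- NULL
  flat <- 0

  forward_eval <- function(p, fmat) {
    sol <- deSolve::ode(as_state(ics), t_model, vdp_desolve,
                        vfo_params(p[1], max(p[2], 1e-3), p[3]),
                        method = "ode45", rtol = 1e-8, atol = 1e-10)
    if (!all(is.finite(sol))) return(NULL)
    traj <- new_vfo_trajectory(sol[, 1], sol[, 2], sol[, 3], sol[, 4],
                               sol[, 5], timescale)
    u0 <- geom$c_tilde * geom$d * (2 * geom$xi0 + traj$xi_l + traj$xi_r)
    uL <- .wave_leapfrog(u0, numeric(0), fmat, cfg$nx, cfg$cfl^2,
                         cfg$dt^2, cfg$dx,
                         cfg$lip_bc == "absorbing")[cfg$nx + 1, ]
    sduL <- stats::sd(uL)
    if (!is.finite(sduL) || sduL == 0) return(NULL)
    uLn <- (uL - mean(uL)) / sduL
    list(traj = traj, u0 = u0, uL = uL, uLn = uLn,
         F = sum(w * (uLn - umz)^2))
  }
  lip_loss <- function(u0, fmat) {
    uL <- .wave_leapfrog(u0, numeric(0), fmat, cfg$nx, cfg$cfl^2,
                         cfg$dt^2, cfg$dx,
                         cfg$lip_bc == "absorbing")[cfg$nx + 1, ]
    sum(w * (standardize(uL) - umz)^2)
  }

  for (it in seq_len(opt$max_iter)) {
    ev <- forward_eval(p, fmat)
    if (is.null(ev)) {
      if (is.null(best)) stop("forward model diverged at initialization",
                              call. = FALSE)
      p <- (p + best$p) / 2
      step <- step / 2
      next
    }
    loss_history <- c(loss_history, ev$F)
    if (is.null(best) || ev$F < best$F) {
      best <- list(F = ev$F, p = p, fmat = fmat, ev = ev)
    }
    dFduL <- normalized_l2_grad(ev$uL, umz, w)

    # profile update: time-reversed propagation of the residual gradient,
    # monotone backtracking on the step length (Landweber iteration)
    for (pu in seq_len(profile_updates)) {
      z <- propagate_time_reversed(-dFduL / w, NULL, cfg)$z
      zmax <- max(abs(z))
      if (zmax > 0) {
        # start deliberately large; backtracking finds the stable scale once
        # and mild growth tracks it afterwards
        if (is.null(iota)) iota <- 1e6 / zmax
        Fn <- Inf
        repeat {
          Fn <- lip_loss(ev$u0, fmat + iota * z)
          if (Fn < ev$F || iota < 1e3 * .Machine$double.eps / zmax) break
          iota <- iota / 2
        }
        if (Fn < ev$F) {
          fmat <- fmat + iota * z
          iota <- iota * 1.5
        }
        if (pu < profile_updates) {
          ev2 <- forward_eval(p, fmat)
          if (!is.null(ev2)) { ev <- ev2; dFduL <- normalized_l2_grad(ev$uL, umz, w) }
        }
      }
    }

    # parameter update via the backprojected residual
    dFdu0 <- wave_transpose_lip_to_glottis(dFduL, cfg)
    Reff <- dFdu0 / (2 * wm)
    adj <- solve_adjoint(ev$traj, vfo_params(p[1], max(p[2], 1e-3), p[3]),
                         Reff, geom)
    g <- vfo_gradients(ev$traj, adj)
    nh <- length(loss_history)
    if (nh >= 2) {
      rel <- abs(loss_history[nh] - loss_history[nh - 1]) /
        max(abs(loss_history[nh]), .Machine$double.xmin)
      flat <- if (rel < opt$loss_tol) flat + 1 else 0
      if (flat >= 3) break
    }
    if (max(abs(g[fit_mask])) < opt$grad_tol) break
    sg <- sign(g)
    agree <- sg * sign(gprev)
    upd <- switch(opt$step_rule,
      rprop = {
        step <- ifelse(agree > 0, pmin(step * 1.2, 10 * opt$step_scale),
                       ifelse(agree < 0, step * 0.5, step))
        gprev <- g
        sg * step
      },
      adaptive_max = opt$step_scale / max(abs(g[fit_mask])) * g,
      fixed = opt$step_scale * g)
    p <- p - ifelse(fit_mask, upd, 0)
    p[2] <- max(p[2], 1e-3)
  }

  p <- best$p
  if (p[3] < 0) p[3] <- -p[3]
  structure(list(params = vfo_params(p[1], p[2], p[3]),
                 profile = vt_profile(best$fmat, cfg),
                 loss_history = loss_history,
                 u0 = best$ev$u0, uL = best$ev$uL, um = umz,
                 t_phys = t_phys, t_model = t_model,
                 timescale = timescale,
                 converged = flat >= 3,
                 n_iter = length(loss_history)),
            class = "adles_vft_fit")
}

#' @export
print.adles_vft_fit <- function(x, ...) {
  cat(sprintf("ADLES-VFT fit: %d iterations, final loss %.4g (%s), f0 = %.4g Hz\n",
              x$n_iter, min(x$loss_history),
              if (x$converged) "converged" else "iteration cap",
              x$timescale$f0))
  print(x$params)
  invisible(x)
}
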