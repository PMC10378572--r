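#' Optimizer configuration for the adjoint fitters
#'
#' @param init_params starting [vfo_params]; the default `(0.8, 0.32, 1.0)`
#'   is the empirical initialization recommended for voice fitting
#' @param step_rule `"rprop"` (sign-based per-parameter step adaptation, the
#'   default), `"adaptive_max"` (a fixed-length step
#'   `step_scale / max(|F_alpha|, |F_beta|, |F_delta|)` along the gradient),
#'   or `"fixed"` (constant step `step_scale` times the gradient)
#' @param step_scale base step size, default 0.01
#' @param max_iter iteration cap, default 200
#' @param loss_tol relative loss-change threshold: stop when the relative
#'   change stays below it for 3 consecutive iterations
#' @param grad_tol gradient infinity-norm threshold
#' @return an object of class `optimizer_config`
#' @export
optimizer_config <- function(init_params = vfo_params(0.8, 0.32, 1.0),
                             step_rule = c("rprop", "adaptive_max", "fixed"),
                             step_scale = 0.01, max_iter = 200,
                             loss_tol = 1e-6, grad_tol = 1e-12) {
  stopifnot(max_iter >= 1, step_scale > 0, loss_tol > 0, grad_tol >= 0)
  structure(list(init_params = init_params,
                 step_rule = match.arg(step_rule),
                 step_scale = step_scale, max_iter = max_iter,
                 loss_tol = loss_tol, grad_tol = grad_tol),
            class = "optimizer_config")
}

#' Residual and squared-error loss between two glottal flows
#'
#' Computes the pointwise residual `R = u0 - ug` and the integrated squared
#' error `F = integral R^2 dt` by trapezoidal quadrature. If the two flows
#' are sampled on different grids, `ug` is linearly resampled onto the grid
#' of `u0`; the durations must agree to within one sample. With
#' `normalize = TRUE` both series are standardized to zero mean and unit
#' variance before differencing (used when the two flows are in unrelated
#' units).
#'
#' @param u0 model flow (`glottal_flow` or data frame with `t`, `u0`)
#' @param ug reference flow (same layout; second column taken as the flow)
#' @param normalize standardize both series first? default `FALSE`
#' @return list with `R` (residual series), `F` (scalar loss), `t` (grid)
#' @export
glottal_residual_loss <- function(u0, ug, normalize = FALSE) {
  t0 <- u0$t; x <- u0[[2]]
  tg <- ug$t; y <- ug[[2]]
  if (length(t0) != length(tg) || max(abs(range(t0) - range(tg))) >
      1.5 * max(diff(t0))) {
    if (abs(diff(range(t0)) - diff(range(tg))) > 1.5 * max(diff(t0))) {
      stop("incompatible durations between u0 and ug", call. = FALSE)
    }
    y <- stats::approx(tg, y, xout = t0, rule = 2)$y
  } else if (any(t0 != tg)) {
    y <- stats::approx(tg, y, xout = t0, rule = 2)$y
  }
  if (normalize) { x <- standardize(x); y <- standardize(y) }
  R <- x - y
  list(R = R, F = trapz(t0, R^2), t = t0)
}

# Adjoint integration shared by the glottal (ADLES) and lip (ADLES-VFT)
# modes. `Reff` is the effective residual density: the adjoint pair
# (lambda, eta) solves, backward from zero terminal conditions at t = T,
#   lambda'' - beta (1+xi_r^2) lambda' + alpha (lambda' + eta') +
#     (1 - delta/2) lambda + 2 c~ d Reff = 0
#   eta''    - beta (1+xi_l^2) eta'    + alpha (lambda' + eta') +
#     (1 + delta/2) eta    + 2 c~ d Reff = 0
# which is the stationarity condition of the constrained least-squares
# Lagrangian with respect to the fold displacements. The commonly printed
# algebraic-companion form (adjoint_form = "algebraic") replaces the
# first-derivative terms using the algebraic relations
#   beta (1+xi_r^2) lambda = alpha (lambda + eta)
#   beta (1+xi_l^2) eta    = alpha (lambda + eta)
# and is equivalent exactly where those relations hold; their pointwise
# residuals are reported as diagnostics in either mode.
solve_adjoint <- function(traj, params, Reff, geom,
                          adjoint_form = c("variational", "algebraic"),
                          rtol = 1e-8, atol = 1e-10) {
  adjoint_form <- match.arg(adjoint_form)
  times <- traj$t
  n <- length(times)
  Tend <- times[n]
  cd2 <- 2 * geom$c_tilde * geom$d
  xr <- stats::splinefun(times, traj$xi_r)
  xl <- stats::splinefun(times, traj$xi_l)
  vr <- stats::splinefun(times, traj$v_r)
  vl <- stats::splinefun(times, traj$v_l)
  Rf <- stats::splinefun(times, Reff)
  a <- params$alpha; b <- params$beta; d2 <- params$delta / 2
  rhs <- if (adjoint_form == "variational") {
    function(tt, y) {
      forcing <- cd2 * Rf(tt)
      c(y[2],
        b * (1 + xr(tt)^2) * y[2] - a * (y[2] + y[4]) - (1 - d2) * y[1] - forcing,
        y[4],
        b * (1 + xl(tt)^2) * y[4] - a * (y[2] + y[4]) - (1 + d2) * y[3] - forcing)
    }
  } else {
    function(tt, y) {
      forcing <- cd2 * Rf(tt)
      c(y[2],
        -(2 * b * xr(tt) * vr(tt) + 1 - d2) * y[1] - forcing,
        y[4],
        -(2 * b * xl(tt) * vl(tt) + 1 + d2) * y[3] - forcing)
    }
  }
  # integrate backward via tau = T - t (explicit RK needs increasing grids)
  adj_tau <- function(tau, y, p) list(-rhs(Tend - tau, y))
  asol <- deSolve::ode(c(0, 0, 0, 0), Tend - rev(times), adj_tau, NULL,
                       method = "ode45", rtol = rtol, atol = atol)
  if (!all(is.finite(asol))) {
    stop("adjoint backward integration diverged", call. = FALSE)
  }
  lam <- rev(asol[, 2]); lam_dot <- -rev(asol[, 3])
  eta <- rev(asol[, 4]); eta_dot <- -rev(asol[, 5])
  alg_r <- b * (1 + traj$xi_r^2) * lam - a * (lam + eta)
  alg_l <- b * (1 + traj$xi_l^2) * eta - a * (lam + eta)
  structure(list(t = times, lam = lam, lam_dot = lam_dot,
                 eta = eta, eta_dot = eta_dot,
                 algebraic_residuals = cbind(right = alg_r, left = alg_l)),
            class = "adjoint_trajectory")
}

#' Adjoint states for a glottal-flow residual
#'
#' Solves the adjoint (costate) system of the fold oscillator driven by a
#' glottal-flow residual, backward in time from zero terminal conditions.
#' See [fit_adles] for the surrounding algorithm.
#'
#' @param traj the forward `vfo_trajectory`
#' @param params the [vfo_params] used for the forward solve
#' @param R residual series on the trajectory grid (`u0 - ug`)
#' @param geom the [fold_geometry]
#' @param adjoint_form `"variational"` (default; gradients match finite
#'   differences of the loss) or `"algebraic"` (the literal algebraic-companion form)
#' @return an `adjoint_trajectory`: `t`, `lam`, `lam_dot`, `eta`, `eta_dot`,
#'   and a two-column matrix `algebraic_residuals` with the pointwise values
#'   of the algebraic companion relations (diagnostics)
#' @export
solve_adjoint_glottal <- function(traj, params, R, geom = fold_geometry(),
                                  adjoint_form = c("variational", "algebraic")) {
  solve_adjoint(traj, params, R, geom, match.arg(adjoint_form))
}

#' Loss gradients from forward and adjoint trajectories
#'
#' The three parameter derivatives of the squared-residual loss,
#' evaluated by trapezoidal quadrature:
#' `F_alpha = int -(v_r + v_l)(lambda + eta) dt`,
#' `F_beta  = int (1+xi_r^2) v_r lambda + (1+xi_l^2) v_l eta dt`,
#' `F_delta = int (xi_l eta - xi_r lambda)/2 dt`.
#'
#' @param traj the forward `vfo_trajectory`
#' @param adj the matching `adjoint_trajectory`
#' @return named numeric vector `(F_alpha, F_beta, F_delta)`
#' @export
vfo_gradients <- function(traj, adj) {
  stopifnot(length(traj$t) == length(adj$t))
  t <- traj$t
  c(F_alpha = trapz(t, -(traj$v_r + traj$v_l) * (adj$lam + adj$eta)),
    F_beta = trapz(t, (1 + traj$xi_r^2) * traj$v_r * adj$lam +
                      (1 + traj$xi_l^2) * traj$v_l * adj$eta),
    F_delta = trapz(t, 0.5 * (traj$xi_l * adj$eta - traj$xi_r * adj$lam)))
}

# One evaluation of the ADLES objective and gradient at `params`.
adles_eval <- function(params, ics, times, ug_vals, geom, normalize,
                       timescale, rtol = 1e-8, atol = 1e-10) {
  sol <- deSolve::ode(as_state(ics), times, vdp_desolve, params,
                      method = "ode45", rtol = rtol, atol = atol)
  if (!all(is.finite(sol))) return(NULL)
  traj <- new_vfo_trajectory(sol[, 1], sol[, 2], sol[, 3], sol[, 4], sol[, 5],
                             timescale)
  u0 <- geom$c_tilde * geom$d * (2 * geom$xi0 + traj$xi_l + traj$xi_r)
  w <- trapz_weights(times)
  if (normalize) {
    ugn <- standardize(ug_vals)
    Fv <- sum(w * (standardize(u0) - ugn)^2)
    Reff <- normalized_l2_grad(u0, ugn, w) / (2 * w)
  } else {
    R <- u0 - ug_vals
    Fv <- sum(w * R^2)
    Reff <- R
  }
  list(traj = traj, u0 = u0, F = Fv, Reff = Reff)
}

# Shared gradient-descent driver. `evaluate(params)` returns list(F=, ...,
# Reff=, traj=) or NULL on divergence; `gradient(ev, params)` returns the
# triple. Returns the best-loss iterate.
descend_params <- function(opt, evaluate, gradient, fit_mask = c(TRUE, TRUE, TRUE),
                           beta_floor = 1e-3, on_iterate = NULL) {
  p <- c(opt$init_params$alpha, opt$init_params$beta, opt$init_params$delta)
  step <- rep(opt$step_scale, 3)
  gprev <- c(0, 0, 0)
  loss_history <- numeric(0)
  best <- list(F = Inf, p = p, ev = NULL)
  flat <- 0
  n_fail <- 0
  for (it in seq_len(opt$max_iter)) {
    ev <- evaluate(p)
    if (is.null(ev)) {
      n_fail <- n_fail + 1
      if (n_fail >= 3 || it == 1) {
        stop(structure(class = c("adles_divergence", "error", "condition"),
                       list(message = "all iterations diverged",
                            call = NULL, loss_history = loss_history)))
      }
      # retreat halfway toward the best-known point and shrink steps
      p <- (p + best$p) / 2
      step <- step / 2
      next
    }
    loss_history <- c(loss_history, ev$F)
    if (ev$F < best$F) best <- list(F = ev$F, p = p, ev = ev)
    if (!is.null(on_iterate)) on_iterate(it, p, ev)
    g <- gradient(ev, p)
    if (max(abs(g[fit_mask])) < opt$grad_tol) break
    nh <- length(loss_history)
    if (nh >= 2) {
      rel <- abs(loss_history[nh] - loss_history[nh - 1]) /
        max(abs(loss_history[nh]), .Machine$double.xmin)
      flat <- if (rel < opt$loss_tol) flat + 1 else 0
      if (flat >= 3) break
    }
    upd <- switch(opt$step_rule,
      rprop = {
        sg <- sign(g)
        agree <- sg * sign(gprev)
        step <- ifelse(agree > 0, pmin(step * 1.2, 10 * opt$step_scale),
                       ifelse(agree < 0, step * 0.5, step))
        gprev <- g
        sg * step
      },
      adaptive_max = opt$step_scale / max(abs(g[fit_mask])) * g,
      fixed = opt$step_scale * g)
    p <- p - ifelse(fit_mask, upd, 0)
    p[2] <- max(p[2], beta_floor)
  }
  list(params = best$p, ev = best$ev, loss_history = loss_history,
       n_iter = length(loss_history),
       converged = flat >= 3 || (length(loss_history) < opt$max_iter))
}

#' Fit the fold-oscillator parameters to a reference glottal flow (ADLES)
#'
#' Adjoint least-squares estimation: iterate (1) forward integration of the
#' oscillator at the current `(alpha, beta, delta)`, (2) backward adjoint
#' integration driven by the flow residual, (3) quadrature of the three
#' parameter gradients, (4) a gradient-descent update, until the loss
#' stabilizes. The time grid of `ug` is used as the simulation grid and is
#' interpreted in model-time units (see [time_scale] for conversion from
#' seconds). The fitted `delta` is reported with the non-negative sign
#' convention (the model is invariant under negating `delta` and swapping
#' the folds).
#'
#' @param ug reference glottal flow: `glottal_flow` or data frame with
#'   columns `t` (model time) and a flow column
#' @param geom the [fold_geometry] (fixed, not estimated)
#' @param ics the known/assumed [vfo_ics]
#' @param opt an [optimizer_config]
#' @param normalize standardize flows before differencing (use when `ug` has
#'   arbitrary units, e.g. from inverse filtering); default `FALSE`: in
#'   consistent units the residual retains the amplitude information that
#'   identifies `alpha` and `beta`
#' @param adjoint_form see [solve_adjoint_glottal]
#' @return an `adles_fit`: `params` ([vfo_params]), `loss_history`,
#'   `final_trajectory`, `final_flow`, `converged`, `n_iter`
#' @examples
#' \donttest{
#' truth <- vfo_params(0.5, 0.32, 0.2)
#' case <- synth_glottal_case(truth, duration = 30)
#' fit <- fit_adles(case$ug, opt = optimizer_config(max_iter = 40))
#' fit$params
#' }
#' @export
fit_adles <- function(ug, geom = fold_geometry(), ics = vfo_ics(),
                      opt = optimizer_config(), normalize = FALSE,
                      adjoint_form = c("variational", "algebraic")) {
  adjoint_form <- match.arg(adjoint_form)
  stopifnot(nrow(ug) > 1)
  times <- ug$t
  ug_vals <- ug[[2]]
  timescale <- attr(ug, "timescale")
  if (is.null(timescale)) timescale <- time_scale()
  res <- descend_params(
    opt,
    evaluate = function(p)
      adles_eval(vfo_params(p[1], max(p[2], 1e-3), p[3]), ics, times,
                 ug_vals, geom, normalize, timescale),
    gradient = function(ev, p) {
      adj <- solve_adjoint(ev$traj, vfo_params(p[1], max(p[2], 1e-3), p[3]),
                           ev$Reff, geom, adjoint_form)
      vfo_gradients(ev$traj, adj)
    })
  p <- res$params
  if (p[3] < 0) p[3] <- -p[3]  # delta sign convention
  flow <- data.frame(t = times, u0 = res$ev$u0)
  attr(flow, "timescale") <- timescale
  class(flow) <- c("glottal_flow", "data.frame")
  structure(list(params = vfo_params(p[1], p[2], p[3]),
                 loss_history = res$loss_history,
                 final_trajectory = res$ev$traj,
                 final_flow = flow,
                 converged = res$converged,
                 n_iter = res$n_iter),
            class = "adles_fit")
}

#' @export
print.adles_fit <- function(x, ...) {
  cat(sprintf("ADLES fit: %d iterations, final loss %.4g (%s)\n",
              x$n_iter, min(x$loss_history),
              if (x$converged) "converged" else "iteration cap"))
  print(x$params)
  invisible(x)
}
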