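#' Poincare-section configuration
#'
#' The section is the zero-velocity hyperplane of one fold
#' (`xi_dot = 0`), so crossings in the `pos_to_neg` direction are the
#' displacement maxima of that fold. Crossing displacement values are
#' clustered with a relative tolerance; the number of clusters is the
#' period count of the steady orbit, and a cluster count above
#' `torus_cluster_cap` is taken as evidence of a torus (quasi-periodic
#' orbit filling a band of the section).
#'
#' @param section which fold's velocity defines the section
#' @param direction crossing direction of the velocity
#' @param transient_fraction leading fraction of the trajectory discarded
#' @param cluster_tol tolerance for distinct crossing values, relative to
#'   the steady oscillation amplitude
#' @param torus_cluster_cap cluster count above which a torus is declared
#' @return an object of class `poincare_config`
#' @export
poincare_config <- function(section = c("right", "left"),
                            direction = c("pos_to_neg", "neg_to_pos"),
                            transient_fraction = 0.75,
                            cluster_tol = 1e-2,
                            torus_cluster_cap = 12) {
  stopifnot(transient_fraction >= 0, transient_fraction < 1, cluster_tol > 0)
  structure(list(section = match.arg(section),
                 direction = match.arg(direction),
                 transient_fraction = transient_fraction,
                 cluster_tol = cluster_tol,
                 torus_cluster_cap = torus_cluster_cap),
            class = "poincare_config")
}

# single-linkage clustering of sorted 1-d values with absolute gap tol
count_clusters <- function(vals, tol) {
  if (length(vals) == 0) return(0L)
  s <- sort(vals)
  if (length(s) == 1) return(1L)
  sum(diff(s) > tol) + 1L
}

# sub-sample crossing times/values of v through 0 in the given direction,
# with displacement x interpolated at the crossing
section_crossings <- function(t, x, v, direction) {
  n <- length(v)
  if (direction == "pos_to_neg") {
    idx <- which(v[-n] > 0 & v[-1] <= 0)
  } else {
    idx <- which(v[-n] < 0 & v[-1] >= 0)
  }
  idx <- idx[v[idx] != v[idx + 1]]
  frac <- v[idx] / (v[idx] - v[idx + 1])
  list(times = t[idx] + frac * (t[idx + 1] - t[idx]),
       values = x[idx] + frac * (x[idx + 1] - x[idx]))
}

post_transient <- function(traj, cfg) {
  t0 <- traj$t[1] + cfg$transient_fraction * (traj$t[nrow(traj)] - traj$t[1])
  traj[traj$t >= t0, , drop = FALSE]
}

#' Poincare-section crossings of a fold trajectory
#'
#' Detects zero crossings of the selected fold's velocity (after discarding
#' the transient) with sub-sample accuracy by linear interpolation, and
#' clusters the crossing displacements with single linkage at
#' `cluster_tol` times the steady amplitude.
#'
#' @param traj a `vfo_trajectory`
#' @param cfg a [poincare_config]
#' @return a `crossing_set`: `times`, `values`, `n_clusters`, `amplitude`,
#'   and `oscillatory` (FALSE when no crossings were found)
#' @export
poincare_crossings <- function(traj, cfg = poincare_config()) {
  tr <- post_transient(traj, cfg)
  if (cfg$section == "right") {
    x <- tr$xi_r; v <- tr$v_r
  } else {
    x <- tr$xi_l; v <- tr$v_l
  }
  cr <- section_crossings(tr$t, x, v, cfg$direction)
  amp <- diff(range(x))
  ncl <- if (amp > 0) count_clusters(cr$values, cfg$cluster_tol * amp)
         else length(cr$values) > 0
  structure(list(times = cr$times, values = cr$values,
                 n_clusters = as.integer(ncl), amplitude = amp,
                 oscillatory = length(cr$times) > 0),
            class = "crossing_set")
}

reduce_ratio <- function(n, m) {
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(n, m)
  c(n = as.integer(n / d), m = as.integer(m / d))
}

#' Entrainment ratio of the two folds
#'
#' Counts Poincare-section crossings of the right and left folds over the
#' same post-transient window and reduces the pair by their greatest common
#' divisor. For 1:1 phase locking the counts agree; n:m locking and drift
#' show up as non-unit ratios.
#'
#' @param traj a `vfo_trajectory`
#' @param cfg a [poincare_config] (its `section` field is ignored; both
#'   folds are counted)
#' @return an `entrainment_ratio`: integers `n` (right), `m` (left),
#'   reduced, plus the raw counts
#' @export
entrainment_ratio <- function(traj, cfg = poincare_config()) {
  tr <- post_transient(traj, cfg)
  nr <- length(section_crossings(tr$t, tr$xi_r, tr$v_r, cfg$direction)$times)
  nl <- length(section_crossings(tr$t, tr$xi_l, tr$v_l, cfg$direction)$times)
  if (nr == 0 || nl == 0) {
    stop("undefined entrainment: a fold has no section crossings",
         call. = FALSE)
  }
  red <- reduce_ratio(nr, nl)
  structure(list(n = red[["n"]], m = red[["m"]],
                 count_right = nr, count_left = nl),
            class = "entrainment_ratio")
}

#' @export
print.entrainment_ratio <- function(x, ...) {
  cat(sprintf("entrainment %d:%d (raw crossing counts %d:%d)\n",
              x$n, x$m, x$count_right, x$count_left))
  invisible(x)
}

#' Full dynamical summary of a fold trajectory
#'
#' Period counts for both folds, entrainment ratio, torus flag (cluster
#' count above the configured cap on either fold), optional largest
#' Lyapunov exponent and Hurst exponent of the right-fold displacement,
#' and a regime label when `params` is supplied.
#'
#' @param traj a `vfo_trajectory`
#' @param params optional [vfo_params] for regime classification and the
#'   Lyapunov computation
#' @param cfg a [poincare_config]
#' @param lyapunov compute the largest Lyapunov exponent (requires
#'   `params`)? default `FALSE`
#' @param hurst compute the Hurst exponent of `xi_r`? default `FALSE`
#' @return a `dynamics_summary` list
#' @export
characterize_dynamics <- function(traj, params = NULL,
                                  cfg = poincare_config(),
                                  lyapunov = FALSE, hurst = FALSE) {
  right <- poincare_crossings(traj, modify_section(cfg, "right"))
  left <- poincare_crossings(traj, modify_section(cfg, "left"))
  ent <- tryCatch(entrainment_ratio(traj, cfg), error = function(e) NULL)
  torus <- max(right$n_clusters, left$n_clusters) > cfg$torus_cluster_cap
  ly <- if (lyapunov && !is.null(params)) {
    largest_lyapunov(params, ics = vfo_ics())
  } else NA_real_
  hu <- if (hurst) hurst_exponent(post_transient(traj, cfg)$xi_r) else NA_real_
  out <- structure(list(period_count_r = right$n_clusters,
                        period_count_l = left$n_clusters,
                        entrainment = ent, torus = torus,
                        lyap1 = ly, hurst = hu, label = NA_character_),
                   class = "dynamics_summary")
  if (!is.null(params)) out$label <- classify_regime(params, out)
  out
}

modify_section <- function(cfg, section) {
  cfg$section <- section
  cfg
}

#' Bifurcation scan over the coupling and asymmetry parameters
#'
#' Simulates the oscillator on an `(alpha, delta)` grid at fixed `beta` and
#' records the entrainment ratio, period counts and torus flag at each
#' point. Integration failures are recorded (`NA` entries), not fatal.
#'
#' @param alpha_axis,delta_axis numeric grid axes
#' @param beta fixed damping coefficient, default 0.32
#' @param ics,duration,dt simulation settings (see [simulate_vfo])
#' @param cfg a [poincare_config]
#' @return a `bifurcation_grid`: list with the axes and matrices
#'   `ratio` (character "n:m"), `period_r`, `period_l`, `torus`
#'   (rows index `alpha_axis`, columns `delta_axis`)
#' @export
bifurcation_scan <- function(alpha_axis, delta_axis, beta = 0.32,
                             ics = vfo_ics(), duration = 2000, dt = 0.02,
                             cfg = poincare_config()) {
  stopifnot(length(alpha_axis) > 0, length(delta_axis) > 0)
  na <- length(alpha_axis); nd <- length(delta_axis)
  ratio <- matrix(NA_character_, na, nd)
  period_r <- matrix(NA_integer_, na, nd)
  period_l <- matrix(NA_integer_, na, nd)
  torus <- matrix(NA, na, nd)
  for (i in seq_len(na)) {
    for (j in seq_len(nd)) {
      res <- tryCatch({
        traj <- simulate_vfo(vfo_params(alpha_axis[i], beta, delta_axis[j]),
                             ics, duration, dt)
        s <- characterize_dynamics(traj, cfg = cfg)
        list(s = s)
      }, error = function(e) NULL)
      if (is.null(res)) next
      s <- res$s
      if (!is.null(s$entrainment)) {
        ratio[i, j] <- sprintf("%d:%d", s$entrainment$n, s$entrainment$m)
      }
      period_r[i, j] <- s$period_count_r
      period_l[i, j] <- s$period_count_l
      torus[i, j] <- s$torus
    }
  }
  structure(list(alpha_axis = alpha_axis, delta_axis = delta_axis,
                 beta = beta, ratio = ratio, period_r = period_r,
                 period_l = period_l, torus = torus),
            class = "bifurcation_grid")
}

# analytic Jacobian of the fold-oscillator RHS
vdp_jacobian <- function(state, params) {
  xi_r <- state[1]; v_r <- state[2]; xi_l <- state[3]; v_l <- state[4]
  a <- params$alpha; b <- params$beta; d2 <- params$delta / 2
  matrix(c(
    0, 1, 0, 0,
    -2 * b * xi_r * v_r - 1 + d2, -b * (1 + xi_r^2) + a, 0, a,
    0, 0, 0, 1,
    0, a, -2 * b * xi_l * v_l - 1 - d2, -b * (1 + xi_l^2) + a),
    4, 4, byrow = TRUE)
}

#' Largest Lyapunov exponent
#'
#' Benettin's method: the state and a tangent (variational) vector are
#' integrated jointly, the tangent is renormalized at fixed intervals, and
#' the exponent is the average logarithmic growth rate per model-time unit.
#' A transient is discarded before accumulation. For a stable limit cycle
#' the largest exponent is 0 (neutral direction along the flow); negative
#' values indicate a fixed point, positive values chaos.
#'
#' For testing and general use, `system` may be a list with elements
#' `rhs(t, y)`, `jac(t, y)` and `dim` instead of a [vfo_params] object.
#'
#' @param system a [vfo_params] or a custom system description (see above)
#' @param ics a [vfo_ics] (for the oscillator) or numeric initial state
#' @param duration accumulation span in model-time units
#' @param transient discarded leading span
#' @param renorm_interval time between renormalizations
#' @param rtol,atol solver tolerances
#' @return largest Lyapunov exponent (per model-time unit)
#' @export
largest_lyapunov <- function(system, ics = vfo_ics(), duration = 500,
                             transient = 100, renorm_interval = 5,
                             rtol = 1e-8, atol = 1e-10) {
  if (inherits(system, "vfo_params")) {
    params <- system
    rhs <- function(t, y) vdp_rhs(y, params)
    jac <- function(t, y) vdp_jacobian(y, params)
    n <- 4L
    y0 <- if (inherits(ics, "vfo_ics")) as_state(ics) else ics
  } else {
    rhs <- system$rhs; jac <- system$jac; n <- system$dim
    y0 <- ics
    stopifnot(is.numeric(y0), length(y0) == n)
  }
  aug <- function(t, y, p) {
    s <- y[1:n]; v <- y[(n + 1):(2 * n)]
    list(c(rhs(t, s), as.vector(jac(t, s) %*% v)))
  }
  # settle onto the attractor first
  if (transient > 0) {
    tr <- deSolve::ode(y0, c(0, transient), function(t, y, p) list(rhs(t, y)),
                       NULL, method = "ode45", rtol = rtol, atol = atol)
    y0 <- tr[nrow(tr), -1]
  }
  v <- rep(1 / sqrt(n), n)
  nsteps <- ceiling(duration / renorm_interval)
  logsum <- 0
  for (k in seq_len(nsteps)) {
    sol <- deSolve::ode(c(y0, v), c(0, renorm_interval), aug, NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    yv <- sol[nrow(sol), -1]
    if (!all(is.finite(yv))) stop("Lyapunov integration diverged", call. = FALSE)
    y0 <- yv[1:n]
    v <- yv[(n + 1):(2 * n)]
    nv <- sqrt(sum(v^2))
    logsum <- logsum + log(nv)
    v <- v / nv
  }
  logsum / (nsteps * renorm_interval)
}

#' Hurst exponent by corrected rescaled-range analysis
#'
#' Classic R/S analysis over dyadic window sizes with the Anis-Lloyd-Peters
#' small-sample correction: the log rescaled range is regressed against the
#' log window size after subtracting the expected R/S of an uncorrelated
#' series, and 0.5 is added back. Uncorrelated noise gives H near 0.5,
#' persistent series larger values (a smooth trend approaches 1).
#'
#' @param series numeric vector, length at least 1000
#' @param min_window smallest window size, default 32 (smaller windows are
#'   dominated by the small-sample correction)
#' @return Hurst exponent estimate
#' @export
hurst_exponent <- function(series, min_window = 32) {
  n <- length(series)
  stopifnot(n >= 1000)
  if (stats::sd(series) == 0) {
    stop("Hurst exponent undefined for a constant series", call. = FALSE)
  }
  sizes <- 2^(seq.int(floor(log2(min_window)), floor(log2(n / 4))))
  rs <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    m <- sizes[k]
    nb <- n %/% m
    vals <- vapply(seq_len(nb), function(b) {
      x <- series[((b - 1) * m + 1):(b * m)]
      y <- cumsum(x - mean(x))
      s <- stats::sd(x)
      if (s == 0) return(NA_real_)
      (max(y) - min(y)) / s
    }, numeric(1))
    rs[k] <- mean(vals, na.rm = TRUE)
  }
  # expected R/S of iid noise (Anis & Lloyd with Peters' n-1/2 factor)
  ers <- vapply(sizes, function(m) {
    i <- seq_len(m - 1)
    ((m - 0.5) / m) * sum(sqrt((m - i) / i)) / sqrt(m * pi / 2)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  fit <- stats::lm(log2(rs[ok]) - log2(ers[ok]) ~ log2(sizes[ok]))
  0.5 + unname(stats::coef(fit)[2])
}

#' Rule-based pathology regime from model parameters
#'
#' Maps the fitted parameter pair `(delta, alpha)` and the observed phase
#' space behavior to the voice-pathology regimes of the bifurcation
#' diagram: a period-1 cycle at small asymmetry is normal phonation;
#' period-1 and period-2 cycles near `delta = 0.6` indicate neoplasm and
#' phonotrauma respectively; a torus near `delta = 0.85` indicates vocal
#' palsy. `tol` is the half-width of the "approximately equal" bands.
#'
#' @param params a [vfo_params]
#' @param summary a `dynamics_summary` (period counts and torus flag used)
#' @param tol band half-width for approximate parameter matches
#' @return one of `"Normal"`, `"Neoplasm"`, `"Phonotrauma"`, `"VocalPalsy"`,
#'   `"Unknown"`
#' @export
classify_regime <- function(params, summary, tol = 0.05) {
  a <- params$alpha; d <- abs(params$delta)
  near <- function(x, c) abs(x - c) <= tol
  period <- max(summary$period_count_r, summary$period_count_l)
  if (isTRUE(summary$torus) && near(d, 0.85)) return("VocalPalsy")
  if (near(d, 0.6) && near(a, 0.3) && period == 2) return("Phonotrauma")
  if (near(d, 0.6) && near(a, 0.35) && period == 1) return("Neoplasm")
  if (d < 0.5 && a > 0.25 && period == 1) return("Normal")
  "Unknown"
}
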