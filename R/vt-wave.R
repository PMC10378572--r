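#' Vocal-tract acoustic configuration
#'
#' Geometry, medium and discretization for the one-dimensional acoustic wave
#' model of the vocal tract, `u_tt = c^2 u_xx + f(x,t)`, posed on a tube of
#' length `L` from the glottis (`x = 0`) to the lips (`x = L`). Defaults are
#' standard adult cgs values. The explicit leapfrog scheme requires a Courant
#' number `c*dt/dx <= 1`; when `dt` is not given it is set to exactly `dx/c`
#' (Courant number 1), at which the discrete scheme propagates plane waves
#' without dispersion.
#'
#' @param L tract length (cm)
#' @param c speed of sound (cm/s)
#' @param rho air density (g/cm^3)
#' @param A_L lip opening area (cm^2)
#' @param nx number of spatial cells (nx + 1 nodes)
#' @param dt time step (s); default `L/nx/c`
#' @param lip_bc lip boundary condition: `"neumann_zero"` (open-end
#'   zero-gradient, the default) or `"absorbing"` (first-order Sommerfeld)
#' @return an object of class `vt_config`
#' @export
vt_config <- function(L = 17.5, c = 35000, rho = 0.00114, A_L = 2,
                      nx = 50, dt = NULL,
                      lip_bc = c("neumann_zero", "absorbing")) {
  stopifnot(L > 0, c > 0, rho > 0, A_L > 0, nx >= 3)
  lip_bc <- match.arg(lip_bc)
  dx <- L / nx
  if (is.null(dt)) dt <- dx / c
  cfl <- c * dt / dx
  if (cfl > 1 + 1e-9) {
    stop(sprintf("CFL violation: c*dt/dx = %.4g > 1; reduce dt below %.4g s",
                 cfl, dx / c), call. = FALSE)
  }
  structure(list(L = L, c = c, rho = rho, A_L = A_L, nx = nx, dt = dt,
                 dx = dx, cfl = cfl, lip_bc = lip_bc),
            class = "vt_config")
}

#' @export
print.vt_config <- function(x, ...) {
  cat(sprintf(
    "vocal tract: L = %.3g cm, c = %.4g cm/s, %d cells, dt = %.3g us (CFL %.3g), lip: %s\n",
    x$L, x$c, x$nx, x$dt * 1e6, x$cfl, x$lip_bc))
  invisible(x)
}

#' Vocal-tract source profile
#'
#' The distributed source term `f(x, t)` of the wave model, stored on the
#' solver grid as an `(nx + 1) x nt` matrix (rows are nodes from glottis to
#' lip). It absorbs yielding-wall, coupling and radiation effects not carried
#' by the rigid-tube operator; with `f = 0` the model is the Webster horn
#' equation for a uniform tube.
#'
#' @param f numeric matrix `(nx + 1) x nt`, or a single number recycled
#' @param cfg a [vt_config]
#' @param nt number of time samples (needed when `f` is scalar)
#' @return an object of class `vt_profile` (a matrix)
#' @export
vt_profile <- function(f = 0, cfg, nt = NULL) {
  if (is.matrix(f)) {
    stopifnot(nrow(f) == cfg$nx + 1)
  } else {
    stopifnot(length(f) == 1, !is.null(nt))
    f <- matrix(f, cfg$nx + 1, nt)
  }
  stop_if_not_finite(f, "vt_profile")
  structure(f, class = c("vt_profile", "matrix", "array"))
}

empty_profile_matrix <- matrix(numeric(0), 0, 0)

profile_matrix <- function(profile, nt, cfg) {
  if (is.null(profile)) return(empty_profile_matrix)
  p <- unclass(profile)
  stopifnot(is.matrix(p), ncol(p) == nt, nrow(p) == cfg$nx + 1)
  p
}

#' Forward acoustic propagation through the vocal tract
#'
#' Solves `u_tt = c^2 u_xx + f` by an explicit second-order leapfrog scheme
#' with the generated glottal flow as a Dirichlet condition at `x = 0`, the
#' configured lip condition at `x = L`, and zero initial conditions (the
#' tract is at rest when the glottal signal enters it).
#'
#' @param u0 glottal volume velocity sampled at `cfg$dt` (numeric vector, or
#'   a `glottal_flow` whose samples are taken as already on the solver grid)
#' @param profile a [vt_profile] aligned to the grid, or `NULL` for a rigid
#'   tube (`f = 0`)
#' @param cfg a [vt_config]
#' @return an `acoustic_field`: list with the space-time field `u`
#'   (`(nx+1) x nt`), the lip trace `uL`, and the configuration
#' @export
propagate_forward <- function(u0, profile = NULL, cfg = vt_config()) {
  if (inherits(u0, "glottal_flow")) u0 <- u0$u0
  stop_if_not_finite(u0, "u0")
  nt <- length(u0)
  fmat <- profile_matrix(profile, nt, cfg)
  u <- .wave_leapfrog(u0, numeric(0), fmat, cfg$nx,
                      cfg$cfl^2, cfg$dt^2, cfg$dx,
                      cfg$lip_bc == "absorbing")
  if (!all(is.finite(u))) stop("wave solver instability: non-finite field",
                               call. = FALSE)
  structure(list(u = u, uL = u[cfg$nx + 1, ], cfg = cfg),
            class = "acoustic_field")
}

#' Time-reversed propagation of a lip residual
#'
#' Propagates a residual observed at the lips backward through the tract:
#' the wave equation is solved in reversed time with the residual driving a
#' Neumann (flux) condition at the lip, a homogeneous Dirichlet condition at
#' the glottis, and zero conditions at the final time. The returned field is
#' re-ordered to forward time.
#'
#' @param r residual series at the lip, sampled at `cfg$dt`
#' @param profile optional [vt_profile] source (used time-reversed), or `NULL`
#' @param cfg a [vt_config]
#' @return a `time_reversed_field`: list with the field `z` (`(nx+1) x nt`,
#'   forward-time order), the glottal trace `z0 = z[1, ]`, and the config
#' @export
propagate_time_reversed <- function(r, profile = NULL, cfg = vt_config()) {
  stop_if_not_finite(r, "residual")
  nt <- length(r)
  fmat <- profile_matrix(profile, nt, cfg)
  if (nrow(fmat) > 0) fmat <- fmat[, nt:1, drop = FALSE]
  z <- .wave_leapfrog(numeric(nt), rev(r), fmat, cfg$nx,
                      cfg$cfl^2, cfg$dt^2, cfg$dx, FALSE)
  if (!all(is.finite(z))) stop("wave solver instability: non-finite field",
                               call. = FALSE)
  z <- z[, nt:1, drop = FALSE]
  structure(list(z = z, z0 = z[1, ], cfg = cfg),
            class = "time_reversed_field")
}

#' Gradient step on the vocal-tract profile
#'
#' Pointwise update of the source profile from a time-reversed residual
#' field `z` and the current forward field `u`, with learning rate `iota`.
#' The combination of the two fields is configurable:
#' `"z_over_c2_plus_u"` applies `f + iota * (z/c^2 + u)`, `"z_over_c2"`
#' drops the forward-field term, and `"z"` uses the raw time-reversed field
#' (the steepest-descent direction for the lip misfit, up to a positive
#' scale factor).
#'
#' @param profile current [vt_profile]
#' @param z a `time_reversed_field` (or bare matrix)
#' @param u an `acoustic_field` (or bare matrix); ignored for combinations
#'   that do not use it
#' @param iota learning rate, default 1
#' @param combination one of `"z_over_c2_plus_u"`, `"z_over_c2"`, `"z"`
#' @param cfg the [vt_config] (needed for `c`)
#' @return the updated `vt_profile`
#' @export
update_profile <- function(profile, z, u = NULL, iota = 1,
                           combination = c("z_over_c2_plus_u", "z_over_c2", "z"),
                           cfg = vt_config()) {
  combination <- match.arg(combination)
  zm <- if (inherits(z, "time_reversed_field")) z$z else z
  stopifnot(all(dim(zm) == dim(profile)))
  incr <- switch(combination,
    z_over_c2_plus_u = {
      um <- if (inherits(u, "acoustic_field")) u$u else u
      if (is.null(um)) stop("combination needs the forward field u", call. = FALSE)
      stopifnot(all(dim(um) == dim(profile)))
      zm / cfg$c^2 + um
    },
    z_over_c2 = zm / cfg$c^2,
    z = zm)
  vt_profile(unclass(profile) + iota * incr, cfg)
}

#' Lip pressure to volume velocity
#'
#' Linear conversion `u(t) = A_L / (rho * c) * p(t)` between the acoustic
#' pressure at the lips and the corresponding volume velocity.
#'
#' @param p pressure series (dyn/cm^2)
#' @param cfg a [vt_config] supplying `A_L`, `rho`, `c`
#' @return velocity series (cm^3/s)
#' @export
pressure_to_velocity <- function(p, cfg = vt_config()) {
  stop_if_not_finite(p, "pressure")
  cfg$A_L / (cfg$rho * cfg$c) * p
}

#' Inverse of [pressure_to_velocity]
#' @param u velocity series (cm^3/s)
#' @param cfg a [vt_config]
#' @return pressure series (dyn/cm^2)
#' @export
velocity_to_pressure <- function(u, cfg = vt_config()) {
  cfg$rho * cfg$c / cfg$A_L * u
}

# Exact discrete transpose of the linear map (glottal Dirichlet data) ->
# (lip trace) for the rigid tube. The scheme starts from rest and has
# time-invariant coefficients, so the map is a causal discrete convolution;
# the transpose of a lower-triangular Toeplitz matrix is obtained by
# reversing input and output of the same solver.
wave_transpose_lip_to_glottis <- function(b, cfg) {
  fld <- propagate_forward(rev(b), NULL, cfg)
  rev(fld$uL)
}
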