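test_that("zero data give identically zero fields", {
  cfg <- vt_config(nx = 30)
  nt <- 200
  fwd <- propagate_forward(numeric(nt), NULL, cfg)
  expect_equal(max(abs(fwd$u)), 0)
  bwd <- propagate_time_reversed(numeric(nt), NULL, cfg)
  expect_equal(max(abs(bwd$z)), 0)
  # terminal conditions of the time-reversed solve hold exactly
  r <- sin(seq(0, 6 * pi, length.out = nt))
  z <- propagate_time_reversed(r, NULL, cfg)
  expect_equal(max(abs(z$z[, nt])), 0)
  expect_equal(max(abs(z$z[, nt] - z$z[, nt - 1])), 0)
})

test_that("rigid-tube forward solve matches the d'Alembert solution", {
  L <- 17.5; cs <- 35000; nx <- 400
  dx <- L / nx
  # run below the Courant limit so genuine discretization error is measured
  cfg <- vt_config(nx = nx, dt = 0.95 * dx / cs)
  nt <- floor(2 * L / cs * 0.9 / cfg$dt)
  t <- (0:(nt - 1)) * cfg$dt
  om <- 2 * pi * 2000
  a <- sin(om * t)
  fld <- propagate_forward(a, NULL, cfg)
  x <- L / 2
  ix <- round(nx / 2) + 1
  sel <- t > 0 & t < (2 * L - x) / cs        # before the first reflection
  exact <- ifelse(t - x / cs >= 0, sin(om * (t - x / cs)), 0)
  err <- sqrt(mean((fld$u[ix, sel] - exact[sel])^2)) /
    sqrt(mean(exact[sel]^2))
  expect_lt(err, 0.02)

  # second-order convergence: doubling resolution cuts the error ~4x.
  # A smooth (windowed) pulse is used: the abrupt wavefront of a switched-on
  # sine limits the observable order at the front.
  pulse <- function(t) sin(om * t) * exp(-((t - 2.5e-4) / 1e-4)^2)
  err_at <- function(nx) {
    dx <- L / nx
    cfg <- vt_config(nx = nx, dt = 0.95 * dx / cs)
    nt <- floor(2 * L / cs * 0.9 / cfg$dt)
    t <- (0:(nt - 1)) * cfg$dt
    fld <- propagate_forward(pulse(t), NULL, cfg)
    ix <- round(nx / 2) + 1
    sel <- t > 0 & t < (2 * L - L / 2) / cs
    exact <- ifelse(t - (L / 2) / cs >= 0, pulse(t - (L / 2) / cs), 0)
    sqrt(mean((fld$u[ix, sel] - exact[sel])^2)) / sqrt(mean(exact[sel]^2))
  }
  ratio <- err_at(100) / err_at(200)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})

test_that("discrete adjoint identity holds to near machine precision", {
  cfg <- vt_config(nx = 50)
  set.seed(42)
  a <- rnorm(200)
  b <- rnorm(200)
  lhs <- sum(propagate_forward(a, NULL, cfg)$uL * b)
  rhs <- sum(a * backproject_residual(b, cfg = cfg)$Rg)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("the forward operator is affine in the glottal data", {
  cfg <- vt_config(nx = 25)
  nt <- 300
  set.seed(3)
  a <- rnorm(nt); b <- rnorm(nt)
  f <- vt_profile(matrix(rnorm((cfg$nx + 1) * nt), cfg$nx + 1, nt), cfg)
  u_ab <- propagate_forward(a + b, f, cfg)$u
  u_a <- propagate_forward(a, f, cfg)$u
  u_b <- propagate_forward(b, f, cfg)$u
  u_0 <- propagate_forward(numeric(nt), f, cfg)$u   # pure source response
  expect_equal(u_ab, u_a + u_b - u_0, tolerance = 1e-12)
})

test_that("bounded input keeps the field bounded over half a second", {
  cfg <- vt_config(nx = 25)
  nt <- round(0.5 / cfg$dt)
  t <- (0:(nt - 1)) * cfg$dt
  fld <- propagate_forward(sin(2 * pi * 150 * t), NULL, cfg)
  expect_true(all(is.finite(fld$u)))
  expect_lt(max(abs(fld$u)), 1e3)
  # CFL violations are refused up front
  expect_error(vt_config(nx = 25, dt = 1.1 * (17.5 / 25) / 35000), "CFL")
})

test_that("profile update arithmetic and descent", {
  cfg <- vt_config(nx = 25)
  nt <- 400
  f0 <- vt_profile(0, cfg, nt)
  zero <- matrix(0, cfg$nx + 1, nt)
  expect_equal(unclass(update_profile(f0, zero, zero, cfg = cfg)),
               unclass(f0))

  # one small descent step on a source-recovery case reduces the lip misfit
  t <- (0:(nt - 1)) * cfg$dt
  a <- sin(2 * pi * 2000 * t)
  xg <- seq(0, cfg$L, length.out = cfg$nx + 1)
  ftrue <- vt_profile(5e8 * outer(sin(pi * xg / cfg$L), rep(1, nt)), cfg)
  um <- propagate_forward(a, ftrue, cfg)$uL
  misfit <- function(f) sum((propagate_forward(a, f, cfg)$uL - um)^2)
  F0 <- misfit(f0)
  r <- um - propagate_forward(a, f0, cfg)$uL
  z <- propagate_time_reversed(r, f0, cfg)
  u <- propagate_forward(a, f0, cfg)
  for (combo in c("z_over_c2_plus_u", "z_over_c2", "z")) {
    dirn <- switch(combo,
                   z_over_c2_plus_u = z$z / cfg$c^2 + u$u,
                   z_over_c2 = z$z / cfg$c^2, z = z$z)
    iota <- 1e-3 * max(abs(unclass(ftrue))) / max(abs(dirn))
    f1 <- update_profile(f0, z, u, iota = iota, combination = combo,
                         cfg = cfg)
    expect_lt(misfit(f1), F0)
  }
})

test_that("pressure-velocity conversion is the printed linear gain", {
  cfg <- vt_config()   # A_L = 2 cm^2, rho = 0.00114, c = 35000
  expect_equal(pressure_to_velocity(0, cfg), 0)
  p <- c(1, -2, 3.5)
  expect_equal(pressure_to_velocity(2 * p, cfg),
               2 * pressure_to_velocity(p, cfg))
  expect_equal(pressure_to_velocity(1, cfg), 2 / (0.00114 * 35000),
               tolerance = 1e-12)
  expect_equal(pressure_to_velocity(1, cfg), 0.05013, tolerance = 1e-3)
  # round trip with the inverse map
  expect_equal(velocity_to_pressure(pressure_to_velocity(p, cfg), cfg), p)
})
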