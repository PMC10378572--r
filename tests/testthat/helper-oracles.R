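# shared oracles and small fixtures, built in code

# fractional Gaussian noise by circulant embedding (independent generator
# oracle for the Hurst estimator)
fgn_oracle <- function(n, H, seed) {
  set.seed(seed)
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  m <- 2 * n
  r <- g(0:n)
  cr <- c(r, r[n:2])
  lam <- Re(stats::fft(cr))
  lam[lam < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n] * sqrt(2)
}

# brute-force quadrature oracle (simple Riemann-trapezoid written
# independently of the package helper)
quad_oracle <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# finite-difference gradient of the ADLES objective
adles_fd_grad <- function(params_vec, ics, ug, geom, normalize, h = 1e-6) {
  loss_at <- function(p) {
    traj <- simulate_vfo(vfo_params(p[1], p[2], p[3]), ics,
                         duration = max(ug$t), dt = ug$t[2] - ug$t[1])
    glottal_residual_loss(glottal_flow(traj, geom), ug,
                          normalize = normalize)$F
  }
  vapply(1:3, function(i) {
    pp <- params_vec; pp[i] <- pp[i] + h
    pm <- params_vec; pm[i] <- pm[i] - h
    (loss_at(pp) - loss_at(pm)) / (2 * h)
  }, numeric(1))
}

# adjoint gradient of the ADLES objective at a parameter point
adles_adjoint_grad <- function(params_vec, ics, ug, geom, normalize) {
  p <- vfo_params(params_vec[1], params_vec[2], params_vec[3])
  traj <- simulate_vfo(p, ics, duration = max(ug$t), dt = ug$t[2] - ug$t[1])
  u0 <- glottal_flow(traj, geom)
  w <- adles:::trapz_weights(ug$t)
  if (normalize) {
    Reff <- adles:::normalized_l2_grad(u0$u0, adles:::standardize(ug$u0), w) /
      (2 * w)
  } else {
    Reff <- u0$u0 - ug$u0
  }
  adj <- solve_adjoint_glottal(traj, p, Reff, geom)
  vfo_gradients(traj, adj)
}

# build a trajectory data frame directly from closed-form components
make_traj <- function(t, xi_r, v_r, xi_l, v_l) {
  adles:::new_vfo_trajectory(t, xi_r, v_r, xi_l, v_l)
}
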