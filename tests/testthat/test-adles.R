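test_that("glottal residual loss has the analytic values", {
  t <- seq(0, 2, by = 0.01)
  u <- data.frame(t = t, u0 = sin(t))
  # identical flows
  r0 <- glottal_residual_loss(u, u)
  expect_equal(r0$R, rep(0, length(t)))
  expect_equal(r0$F, 0)
  # constant offset k over duration T integrates to k^2 T
  k <- 3.2
  r1 <- glottal_residual_loss(data.frame(t = t, u0 = sin(t) + k), u)
  expect_equal(r1$F, k^2 * 2, tolerance = 1e-12)
  # nonnegativity on arbitrary inputs
  set.seed(1)
  r2 <- glottal_residual_loss(data.frame(t = t, u0 = rnorm(length(t))), u)
  expect_gte(r2$F, 0)
  # grid mismatch triggers resampling, not an error
  u_coarse <- data.frame(t = seq(0, 2, by = 0.02), u0 = sin(seq(0, 2, by = 0.02)))
  expect_equal(glottal_residual_loss(u, u_coarse)$F, 0, tolerance = 1e-6)
})

test_that("zero residual forces a zero adjoint with zero terminal values", {
  p <- vfo_params(0.5, 0.32, 0.2)
  tr <- simulate_vfo(p, vfo_ics(0.05, 0.06), duration = 20, dt = 0.02)
  adj <- solve_adjoint_glottal(tr, p, rep(0, nrow(tr)))
  expect_equal(max(abs(adj$lam)), 0)
  expect_equal(max(abs(adj$eta)), 0)
  # nonzero residual: terminal conditions still hold
  adj2 <- solve_adjoint_glottal(tr, p, tr$xi_r)
  n <- length(adj2$lam)
  expect_equal(adj2$lam[n], 0, tolerance = 1e-10)
  expect_equal(adj2$eta[n], 0, tolerance = 1e-10)
  expect_equal(adj2$lam_dot[n], 0, tolerance = 1e-10)
  expect_equal(adj2$eta_dot[n], 0, tolerance = 1e-10)
  # diagnostics surface the algebraic companion relations
  expect_equal(dim(adj2$algebraic_residuals), c(n, 2L))

  # the literal algebraic-companion form integrates with the same terminal
  # conditions but is a genuinely different initial-value problem
  adj3 <- solve_adjoint_glottal(tr, p, tr$xi_r, adjoint_form = "algebraic")
  expect_true(all(is.finite(adj3$lam)))
  expect_equal(adj3$lam[n], 0, tolerance = 1e-10)
  expect_gt(max(abs(adj3$lam - adj2$lam)), 0)
})

test_that("gradient quadratures match an independent quadrature oracle", {
  p <- vfo_params(0.5, 0.32, 0.2)
  tr <- simulate_vfo(p, vfo_ics(0.05, 0.06), duration = 20, dt = 0.02)
  adj <- solve_adjoint_glottal(tr, p, tr$xi_r + 0.5 * tr$v_l)
  g <- vfo_gradients(tr, adj)
  expect_equal(unname(g[1]),
               quad_oracle(tr$t, -(tr$v_r + tr$v_l) * (adj$lam + adj$eta)),
               tolerance = 1e-10)
  expect_equal(unname(g[2]),
               quad_oracle(tr$t, (1 + tr$xi_r^2) * tr$v_r * adj$lam +
                                 (1 + tr$xi_l^2) * tr$v_l * adj$eta),
               tolerance = 1e-10)
  expect_equal(unname(g[3]),
               quad_oracle(tr$t, 0.5 * (tr$xi_l * adj$eta - tr$xi_r * adj$lam)),
               tolerance = 1e-10)
  # zero adjoint annihilates all three gradients
  zadj <- solve_adjoint_glottal(tr, p, rep(0, nrow(tr)))
  expect_equal(unname(vfo_gradients(tr, zadj)), c(0, 0, 0))
})

test_that("adjoint gradients match central finite differences", {
  # three distinct synthetic cases; the defining oracle of the module
  cases <- list(
    list(truth = c(0.50, 0.32, 0.20), eval_at = c(0.55, 0.30, 0.25),
         ics = vfo_ics(0.10, 0.12), normalize = FALSE),
    list(truth = c(0.45, 0.40, 0.00), eval_at = c(0.50, 0.35, 0.10),
         ics = vfo_ics(0.05, 0.05), normalize = FALSE),
    list(truth = c(0.55, 0.25, 0.40), eval_at = c(0.60, 0.30, 0.30),
         ics = vfo_ics(0.08, 0.03), normalize = TRUE))
  for (cs in cases) {
    truth <- vfo_params(cs$truth[1], cs$truth[2], cs$truth[3])
    ug <- synth_glottal_case(truth, cs$ics, duration = 30)$ug
    g <- adles_adjoint_grad(cs$eval_at, cs$ics, ug, fold_geometry(),
                            cs$normalize)
    fd <- adles_fd_grad(cs$eval_at, cs$ics, ug, fold_geometry(),
                        cs$normalize)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-10)), 1e-3)
  }
})

test_that("self-consistent reference gives zero loss at iteration one", {
  init <- vfo_params(0.8, 0.32, 1.0)
  ug <- synth_glottal_case(init, duration = 30)$ug
  fit <- fit_adles(ug, opt = optimizer_config(init_params = init, max_iter = 2))
  expect_lt(fit$loss_history[1], 1e-8)
})

test_that("descent with a small fixed step is monotone on a noiseless case", {
  truth <- vfo_params(0.5, 0.32, 0.2)
  ug <- synth_glottal_case(truth, duration = 30)$ug
  fit <- fit_adles(ug, opt = optimizer_config(
    init_params = vfo_params(0.55, 0.30, 0.25),
    step_rule = "fixed", step_scale = 1e-12, max_iter = 8))
  expect_true(all(diff(fit$loss_history) <= 1e-12 * fit$loss_history[1]))
})

test_that("fits are bitwise reproducible", {
  ug <- synth_glottal_case(vfo_params(0.5, 0.32, 0.2), duration = 20)$ug
  o <- optimizer_config(max_iter = 5)
  f1 <- fit_adles(ug, opt = o)
  f2 <- fit_adles(ug, opt = o)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(unclass(f1$params), unclass(f2$params))
})

test_that("parameters are recovered from a mildly noisy reference", {
  truth <- vfo_params(0.5, 0.32, 0.2)
  case <- synth_glottal_case(truth, duration = 40, noise_sd = 0.01, seed = 11)
  fit <- fit_adles(case$ug, opt = optimizer_config(max_iter = 300))
  est <- c(fit$params$alpha, fit$params$beta, fit$params$delta)
  expect_lt(max(abs(est - c(0.5, 0.32, 0.2)) / c(0.5, 0.32, 0.2)), 0.15)
})
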