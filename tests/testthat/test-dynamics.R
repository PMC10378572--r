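test_that("section crossings of closed-form trajectories", {
  t <- seq(0, 200, by = 0.01)
  # constant trajectory: no crossings, flagged non-oscillatory
  flat <- make_traj(t, rep(1, length(t)), rep(0, length(t)),
                    rep(1, length(t)), rep(0, length(t)))
  cs <- poincare_crossings(flat)
  expect_equal(length(cs$times), 0L)
  expect_false(cs$oscillatory)

  # xi = sin(t): velocity maxima crossings all at xi = 1, one cluster
  sine <- make_traj(t, sin(t), cos(t), sin(t), cos(t))
  cs <- poincare_crossings(sine)
  expect_true(all(abs(cs$values - 1) < 1e-4))
  expect_equal(cs$n_clusters, 1L)

  # crossing counts are invariant under time and amplitude rescaling
  fast <- make_traj(t / 4, sin(t), cos(t), sin(t), cos(t))
  big <- make_traj(t, 50 * sin(t), 50 * cos(t), 50 * sin(t), 50 * cos(t))
  expect_equal(length(poincare_crossings(fast)$times), length(cs$times))
  expect_equal(poincare_crossings(big)$n_clusters, cs$n_clusters)
  expect_equal(length(poincare_crossings(big)$times), length(cs$times))
})

test_that("entrainment from crossing counts, with fold-swap symmetry", {
  t <- seq(0, 400, by = 0.01)
  # right fold oscillates twice as fast: 2:1
  tw <- make_traj(t, sin(2 * t), 2 * cos(2 * t), sin(t), cos(t))
  e <- entrainment_ratio(tw)
  expect_equal(c(e$n, e$m), c(2L, 1L))
  # swapping folds maps n:m to m:n
  sw <- make_traj(t, sin(t), cos(t), sin(2 * t), 2 * cos(2 * t))
  es <- entrainment_ratio(sw)
  expect_equal(c(es$n, es$m), c(1L, 2L))
  # identical series: 1:1
  id <- make_traj(t, sin(t), cos(t), sin(t), cos(t))
  ei <- entrainment_ratio(id)
  expect_equal(c(ei$n, ei$m), c(1L, 1L))
  expect_error(entrainment_ratio(make_traj(t, rep(0, length(t)),
                                           rep(0, length(t)), sin(t), cos(t))),
               "undefined entrainment")
})

test_that("normal-regime trajectory: single cluster, 1:1, labelled Normal", {
  p <- regime_preset("normal")
  traj <- simulate_vfo(p, duration = 600)
  s <- characterize_dynamics(traj, p)
  expect_equal(s$period_count_r, 1L)
  expect_equal(s$period_count_l, 1L)
  expect_equal(c(s$entrainment$n, s$entrainment$m), c(1L, 1L))
  expect_false(s$torus)
  expect_equal(s$label, "Normal")
  # deterministic: identical settings give identical summaries
  s2 <- characterize_dynamics(simulate_vfo(p, duration = 600), p)
  expect_identical(write_summary_json(s), write_summary_json(s2))
})

test_that("bifurcation scan is consistent with pointwise analysis", {
  g1 <- bifurcation_scan(0.5, 0, duration = 400)
  traj <- simulate_vfo(vfo_params(0.5, 0.32, 0), duration = 400)
  e <- entrainment_ratio(traj)
  expect_equal(g1$ratio[1, 1], sprintf("%d:%d", e$n, e$m))
  expect_equal(g1$period_r[1, 1], poincare_crossings(traj)$n_clusters)

  # the symmetric row is all period-1, 1:1
  row <- bifurcation_scan(c(0.3, 0.4, 0.5), 0, duration = 400)
  expect_true(all(row$ratio == "1:1"))
  expect_true(all(row$period_r == 1L))
  expect_true(all(!row$torus))
})

test_that("largest Lyapunov exponent: analytic and attractor cases", {
  # test hook: dx/dt = -x has exponent exactly -1
  lin <- list(rhs = function(t, y) -y,
              jac = function(t, y) matrix(-1, 1, 1), dim = 1L)
  expect_equal(largest_lyapunov(lin, ics = 1, duration = 50, transient = 5),
               -1, tolerance = 0.01)
  # a stable limit cycle has largest exponent 0 (neutral along the flow)
  expect_equal(largest_lyapunov(regime_preset("normal")), 0,
               tolerance = 0.02)
  # the high-asymmetry regime is non-chaotic
  expect_lte(largest_lyapunov(regime_preset("palsy")), 0.02)
})

test_that("Hurst exponent: noise, long memory, persistent limit", {
  set.seed(7)
  expect_equal(hurst_exponent(rnorm(10000)), 0.5, tolerance = 0.05)
  # fractional Gaussian noise with H = 0.7 from the embedding oracle
  # (averaged over realizations: single draws carry sampling noise on top
  # of the rescaled-range bias)
  h_hat <- mean(vapply(1:4, function(s)
    hurst_exponent(fgn_oracle(8192, 0.7, s)), numeric(1)))
  expect_equal(h_hat, 0.7, tolerance = 0.1)
  expect_equal(hurst_exponent(seq_len(5000) / 5000), 1, tolerance = 0.05)
  expect_error(hurst_exponent(rep(1, 2000)), "constant")
})

test_that("regime classification rules cover the labelled parameter regions", {
  s1 <- list(period_count_r = 1L, period_count_l = 1L, torus = FALSE)
  expect_equal(classify_regime(vfo_params(0.4, 0.32, 0.3), s1), "Normal")
  expect_equal(classify_regime(vfo_params(0.35, 0.32, 0.6), s1), "Neoplasm")
  s2 <- list(period_count_r = 2L, period_count_l = 2L, torus = FALSE)
  expect_equal(classify_regime(vfo_params(0.3, 0.32, 0.6), s2), "Phonotrauma")
  st <- list(period_count_r = 20L, period_count_l = 1L, torus = TRUE)
  expect_equal(classify_regime(vfo_params(0.4, 0.32, 0.85), st), "VocalPalsy")
  expect_equal(classify_regime(vfo_params(0.1, 0.32, 0.2), s1), "Unknown")
})
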