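test_that("QR exponents reproduce the rates of an uncoupled linear system", {
  # g_h = 0 kills the activation: h relaxes at sigma_z(0) = 1/2, the gate
  # fields at 1/tau; the spectrum is three flat groups
  p <- network_params(30, g_h = 0, tau_z = 2.5, tau_r = 5, seed = 2)
  ly <- lyapunov_spectrum(make_network(p), k = 90, t_total = 250,
                          t_transient = 60, reorth_interval = 0.5)
  e <- ly$exponents
  expect_true(all(abs(e[1:30] + 0.2) < 1e-3))
  expect_true(all(abs(e[31:60] + 0.4) < 1e-3))
  expect_true(all(abs(e[61:90] + 0.5) < 1e-3))
})

test_that("the spectrum sum matches the time-averaged Jacobian trace", {
  p <- network_params(40, g_h = 3, seed = 9)
  ly <- lyapunov_spectrum(make_network(p), k = 120, t_total = 120,
                          t_transient = 30)
  expect_lt(abs(sum(ly$exponents) - ly$mean_trace) / abs(ly$mean_trace), 0.02)
})

test_that("halving the reorthonormalization interval is inert", {
  net <- make_network(network_params(100, g_h = 3, seed = 12))
  a <- lyapunov_spectrum(net, k = 10, t_total = 220, t_transient = 60,
                         reorth_interval = 1)
  b <- lyapunov_spectrum(net, k = 10, t_total = 220, t_transient = 60,
                         reorth_interval = 0.5)
  expect_lt(max(abs(a$exponents - b$exponents)), 0.01)
})

test_that("kaplan_yorke evaluates the dimension formula", {
  expect_equal(kaplan_yorke(c(-0.1, -0.2)), 0)
  expect_equal(kaplan_yorke(c(0.5, -1)), 1.5)
  expect_equal(kaplan_yorke(c(0.2, 0.1, -0.5)), 2 + 0.3 / 0.5)
  expect_error(kaplan_yorke(c(1, 0.5)), "more exponents")
  expect_error(kaplan_yorke(c(0.1, 0.5)), "nonincreasing")
})

test_that("a sensitive output gate raises dimensionality and chaos", {
  res <- lapply(c(0, 6), function(ar) {
    p <- network_params(200, g_h = 3, alpha_r = ar, seed = 13)
    lyapunov_spectrum(make_network(p), k = 40, t_total = 260, t_transient = 60)
  })
  expect_gt(res[[2]]$exponents[1], 0)
  expect_gt(res[[2]]$ky_dimension, res[[1]]$ky_dimension)
})

test_that("correlators are consistent with the moments and with white noise", {
  p <- network_params(400, g_h = 3, seed = 5)
  tr <- simulate_network(make_network(p), t_final = 260, record_every = 4)
  co <- measure_correlators(tr, max_lag = 10)
  m <- steady_state_moments(tr)
  expect_equal(co$C_h[1], m$h2, tolerance = 1e-10)
  expect_true(all(co$C_h[1] >= abs(co$C_h[-1]) - 1e-12))
  # the weakly chaotic state decorrelates slowly but monotonically
  i10 <- which.min(abs(co$lags - 10))
  expect_lt(co$C_h[i10], 0.96 * co$C_h[1])
  expect_lt(cor(co$lags, co$C_h), -0.9)

  # white-noise surrogate: no temporal structure beyond lag zero
  set.seed(77)
  nt <- 2001; n <- 50
  wn <- structure(list(times = seq(0, 100, by = 0.05),
                       h = matrix(rnorm(nt * n), nt, n),
                       z = matrix(rnorm(nt * n), nt, n),
                       r = matrix(rnorm(nt * n), nt, n),
                       params = network_params(n, g_h = 1),
                       gate_override = NULL, inputs = list(), dt = 0.05,
                       record_every = 1L, effective_alpha_z = 0,
                       effective_alpha_r = 0), class = "trajectory")
  cw <- measure_correlators(wn, max_lag = 2)
  se <- 1 / sqrt(nt / 2 * n)
  expect_true(all(abs(cw$C_h[-1]) < 4 * se))
})

test_that("the mean-field growth-rate eigenproblem has the right sign structure", {
  p_sub <- network_params(300, g_h = 1.5, seed = 7)
  tr <- simulate_network(make_network(p_sub), t_final = 320, record_every = 4)
  co <- measure_correlators(tr, max_lag = 15)
  expect_lt(dmft_lambda_max(co, p_sub), 0)
  expect_error(dmft_lambda_max(co, network_params(300, g_h = 1.5, alpha_z = 2)),
               "alpha_z")
})
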