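test_that("representative points land in their phase-diagram regions", {
  p1 <- classify_point(network_params(150, g_h = 1.2, alpha_r = 1, seed = 2),
                       n_trials = 4L, positive_votes = 3L, t_sim = 80)
  expect_equal(p1$region, 1L)
  expect_false(p1$marginal_overlay)

  p4 <- classify_point(network_params(150, g_h = 3, alpha_r = 0, seed = 2),
                       n_trials = 4L, positive_votes = 3L, t_sim = 80)
  expect_equal(p4$region, 4L)

  p5 <- classify_point(network_params(150, g_h = 3, alpha_r = 0,
                                      alpha_z = Inf, seed = 2),
                       n_trials = 4L, positive_votes = 3L, t_sim = 80)
  expect_equal(p5$region, 4L)
  expect_true(p5$marginal_overlay)
  expect_lt(p5$evidence$rho, 1)

  expect_error(classify_point(network_params(50, g_h = 1, beta_h = 0.5)),
               "bias-free")
})

test_that("a zero-strength input scan is neutral", {
  grid <- data.frame(g_h = 1.5, alpha_r = 2)
  sc <- input_induced_chaos_scan(grid, network_params(80, g_h = 1, seed = 3),
                                 sigma_h = 0, n_trials = 2L,
                                 positive_votes = 2L, t_sim = 60)
  expect_equal(sc$verdict, "neutral")
  expect_equal(sc$lambda_no_input, sc$lambda_with_input, tolerance = 1e-10)
})

test_that("the input-driven critical line passes through the classical point", {
  line0 <- biased_critical_line(0, c(1.99, 2.01, 2.5))
  expect_true(is.na(line0$alpha_r_crit[1]) || line0$alpha_r_crit[1] > 1)
  expect_equal(line0$alpha_r_crit[2], 0)  # just above g = 2: unstable already
  expect_equal(line0$alpha_r_crit[3], 0)

  line <- biased_critical_line(0.5, c(1.8, 2.1, 3.0))
  # drive suppresses chaos along the gain axis: critical gain exceeds 2
  expect_gt(line$alpha_r_crit[2], 0)
  # but a finite alpha_r band below g = 2 becomes chaotic under drive
  expect_true(is.finite(line$alpha_r_crit[1]))
  expect_gt(line$alpha_r_crit[1], line$alpha_r_crit[3])  # dips with gain
})

test_that("stable-regime transients are short and size-independent", {
  tt <- transient_time_scaling(network_params(50, g_h = 1.2, alpha_r = 1,
                                              seed = 4),
                               n_list = c(50, 120), trials = 3L, t_max = 80,
                               init_scale = 0.5)
  expect_true(all(tt$n_collapsed == 3))
  expect_true(all(tt$median_transient < 40))
  expect_lt(abs(tt$median_transient[2] - tt$median_transient[1]), 15)
})

test_that("the output-gate clamp resets the state to zero", {
  p <- network_params(120, g_h = 3, seed = 6)
  r <- reset_experiment(p, "gate_clamp", t_memory = 30, t_reset = 15,
                        t_post = 10)
  iw <- which(r$times >= r$reset_window[1] & r$times <= r$reset_window[2])
  h0 <- r$h_norm[iw[1]]
  expect_gt(h0, 0.5)                       # a memory state was present
  # decay at rate sigma_z = 1/2 over the clamp window
  expect_lt(r$h_norm[tail(iw, 1)], h0 * exp(-0.4 * 15))
  expect_true(all(diff(r$h_norm[iw]) < 1e-8))
})

test_that("zero input leaves no excess projection in the integrator probe", {
  p <- network_params(150, g_h = 3, alpha_z = 30, seed = 4)
  res <- integrator_experiment(p, input_strengths = 0, t_relax = 60,
                               t_post = 60)
  expect_equal(res$plateau[1], 0, tolerance = 1e-10)
})
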