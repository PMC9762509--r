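test_that("Gauss-Hermite averages agree with closed forms and adaptive quadrature", {
  expect_equal(gaussian_average(function(x) x^2, 2), 2, tolerance = 1e-10)
  expect_equal(gaussian_average(function(x) activation_deriv(x, 3)^2, 0), 9)
  # adaptive-integration oracle, bounded integrand
  expect_equal(gaussian_average(function(x) tanh(x)^2, 1),
               oracle_gauss_avg(function(x) tanh(x)^2, 1), tolerance = 1e-9)
  # node doubling is inert: tight for smooth integrands, relative 1e-3 for
  # the strongly peaked sech^4 at large gain
  expect_equal(gaussian_average(function(x) tanh(x)^2, 1, nodes = 201L),
               gaussian_average(function(x) tanh(x)^2, 1, nodes = 401L),
               tolerance = 1e-9)
  f <- function(x) activation_deriv(x, 6.5)^2
  expect_lt(abs(gaussian_average(f, 0.18, nodes = 201L) /
                  gaussian_average(f, 0.18, nodes = 401L) - 1), 1e-3)
  expect_error(gaussian_average(function(x) x, -1), "nonnegative")
})

test_that("the zero branch is exact and the nonzero branch collapses subcritically", {
  z <- solve_fixed_point(network_params(2, g_h = 1.7), init_branch = "zero")
  expect_identical(z$residual, 0)
  expect_identical(z$delta_h, 0)

  sub <- solve_fixed_point(network_params(2, g_h = 1))
  expect_equal(sub$branch, "zero")
  expect_equal(sub$delta_h, 0)
})

test_that("supercritical variances are positive, monotone in gain, and match simulation", {
  sols <- lapply(c(2.2, 2.6, 3.0, 3.6), function(g)
    solve_fixed_point(network_params(2, g_h = g)))
  dh <- vapply(sols, `[[`, numeric(1), "delta_h")
  expect_true(all(dh > 0))
  expect_true(all(diff(dh) > 0))
  expect_equal(dh[3], oracle_delta_h(3.0), tolerance = 1e-6)

  for (g in c(3.0, 3.5)) {
    p <- network_params(800, g_h = g, seed = 21)
    tr <- simulate_network(make_network(p), t_final = 250, record_every = 4)
    m <- steady_state_moments(tr)
    sol <- solve_fixed_point(p)
    expect_lt(abs(sol$delta_h - m$h2) / sol$delta_h, 0.15)
  }
})

test_that("a sensitive output gate creates fixed points below the chaotic gain", {
  s <- solve_fixed_point(network_params(2, g_h = 1.8, alpha_r = 9))
  expect_equal(s$branch, "nonzero")
  expect_gt(s$delta_h, 1e-4)
})

test_that("the fixed-point proliferation threshold behaves like the theory", {
  expect_true(is.na(alpha_r_fp_star(1.0)))
  star <- vapply(c(1.7, 1.8, 1.9), alpha_r_fp_star, numeric(1))
  expect_true(all(is.finite(star)))
  expect_true(all(diff(star) < 0))           # decreasing in gain
  expect_equal(alpha_r_fp_star(2.5), 0)      # already unstable at alpha_r = 0
  # approaching the left edge of the chaotic gain the threshold nears sqrt(8)
  expect_lt(abs(alpha_r_fp_star(1.999) - sqrt(8)), 0.5)
})

test_that("the quenched-drive closures modify the fixed point as documented", {
  p <- network_params(2, g_h = 1.9)
  bias <- solve_fixed_point(p, input_variance_h = 0.25)
  expect_equal(bias$delta_phi_arg, bias$delta_h + 0.25 / 1.9^2)
  expect_gt(bias$delta_h, 0)
  addv <- solve_fixed_point(p, input_variance_h = 0.25,
                            input_mode = "additive_h")
  # additive input enters through sigma_z^{-2} = 4 at alpha_z = 0
  expect_gt(addv$delta_h, 4 * 0.25)
  expect_error(solve_fixed_point(network_params(2, g_h = 1, alpha_z = Inf),
                                 input_variance_h = 0.1,
                                 input_mode = "additive_h"), "alpha_z")
})
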