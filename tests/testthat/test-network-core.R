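test_that("gate_value covers the sigmoid and its Heaviside limit", {
  expect_equal(gate_value(0, 0, 0), 0.5)
  expect_equal(gate_value(0, 7.3, 0), 0.5)
  expect_equal(gate_value(c(-1, 0, 1), Inf, 0), c(0, 0.5, 1))
  expect_equal(gate_value(0, Inf, 1), 1 / (1 + exp(1)))
  expect_equal(gate_deriv(c(-1, 0, 2), Inf, 0), c(0, 0, 0))
  expect_equal(gate_deriv(0, 4, 0), 1)  # alpha * 1/4
  # monotone and bounded
  x <- seq(-5, 5, length.out = 101)
  g <- gate_value(x, 2, 0.7)
  expect_true(all(diff(g) > 0) && all(g >= 0 & g <= 1))
})

test_that("network_params validates its domain", {
  expect_error(network_params(1, g_h = 1), "n_units")
  expect_error(network_params(10, g_h = -1), "g_h")
  expect_error(network_params(10, g_h = 1, tau_z = 0), "tau")
  expect_error(network_params(10, g_h = Inf), "finite")
  p <- network_params(10, g_h = 2, alpha_z = Inf)
  expect_true(is.infinite(p$alpha_z))
})

test_that("coupling draws are seeded, independent, and correctly scaled", {
  p <- network_params(500, g_h = 3, seed = 1)
  n1 <- make_network(p); n2 <- make_network(p)
  expect_identical(n1$J_h, n2$J_h)
  expect_identical(n1$J_z, n2$J_z)
  expect_false(identical(n1$J_h, n1$J_z))

  big <- make_network(network_params(2000, g_h = 1, seed = 3))
  v <- var(as.vector(big$J_h)) * 2000
  expect_gt(v, 0.8); expect_lt(v, 1.2)
  expect_lt(abs(mean(big$J_h)), 4 / sqrt(2000))

  tiny <- make_network(network_params(2, g_h = 1, seed = 7))
  expect_true(all(is.finite(tiny$J_h)) && all(dim(tiny$J_h) == c(2, 2)))
})

test_that("trajectories are deterministic given seeds and decay when g_h = 0", {
  net <- make_network(network_params(80, g_h = 0, seed = 3))
  tr <- simulate_network(net, t_final = 45)
  expect_lt(sqrt(sum(final_state(tr)$h^2)),
            1e-6 * sqrt(sum(tr$h[1, ]^2)))
  tr2 <- simulate_network(net, t_final = 45)
  expect_identical(tr$h, tr2$h)
})

test_that("pinned gates reproduce the classical additive RNN", {
  p <- network_params(100, g_h = 1.3, seed = 5)
  net <- make_network(p, gate_override = list(z = 1, r = 1))
  init <- list(h = rnorm(100, 0, 0.3), z = numeric(100), r = numeric(100))
  set.seed(11); init$h <- rnorm(100, 0, 0.3)
  tr <- simulate_network(net, t_final = 10, dt = 0.02, init = init)
  x_oracle <- oracle_classical_rk4(net$J_h, 1.3, init$h, 10, 0.02)
  expect_lt(max(abs(final_state(tr)$h - x_oracle)), 1e-8)

  # subcritical classical gain: converges to the zero fixed point
  net2 <- make_network(network_params(100, g_h = 0.5, seed = 5),
                       gate_override = list(z = 1, r = 1))
  tr2 <- simulate_network(net2, t_final = 60)
  expect_lt(max(abs(final_state(tr2)$h)), 1e-6)
})

test_that("trajectories stay bounded across regimes", {
  set.seed(99)
  for (i in 1:4) {
    p <- network_params(60, g_h = runif(1, 0, 4), alpha_z = runif(1, 0, 10),
                        alpha_r = runif(1, 0, 10), seed = i)
    net <- make_network(p)
    tr <- simulate_network(net, t_final = 30, init_scale = 1, record_every = 5)
    bound <- max(max(abs(tr$h[1, ])), max(rowSums(abs(net$J_h))) + 1)
    expect_true(all(is.finite(tr$h)))
    expect_lt(max(abs(tr$h)), 1.01 * bound)
  }
})

test_that("halving dt barely changes a smooth trajectory endpoint", {
  net <- make_network(network_params(80, g_h = 1.2, seed = 8))
  set.seed(8)
  init <- list(h = rnorm(80, 0, 0.5), z = rnorm(80, 0, 0.1), r = rnorm(80, 0, 0.1))
  e1 <- final_state(simulate_network(net, t_final = 50, dt = 0.05, init = init))
  e2 <- final_state(simulate_network(net, t_final = 50, dt = 0.025, init = init))
  expect_lt(abs(sqrt(sum(e1$h^2)) - sqrt(sum(e2$h^2))) /
              max(sqrt(sum(e2$h^2)), 1e-12), 0.01)
})

test_that("divergent states raise an integration error naming the time", {
  net <- make_network(network_params(10, g_h = 1, seed = 1))
  bad <- list(h = rep(1e9, 10), z = numeric(10), r = numeric(10))
  expect_error(simulate_network(net, t_final = 1, init = bad), "t = ")
})

test_that("input protocols validate and act only inside their windows", {
  expect_error(input_protocol("h", 1:5, t_on = 2, t_off = 1), "t_on")
  net <- make_network(network_params(40, g_h = 0, seed = 2))
  ip <- input_protocol("h", rep(1, 40), t_on = 5, t_off = 6)
  tr <- simulate_network(net, t_final = 10, inputs = list(ip),
                         init = list(h = numeric(40), z = numeric(40),
                                     r = numeric(40)))
  before <- max(abs(tr$h[tr$times < 5, ]))
  during <- max(abs(tr$h[tr$times >= 5.5 & tr$times < 6, ]))
  expect_equal(before, 0)
  expect_gt(during, 0.3)
})

test_that("steady-state moments at the origin and the burn-in precondition", {
  n <- 30
  net <- make_network(network_params(n, g_h = 3, seed = 1))
  zero_traj <- structure(list(
    times = seq(0, 20, by = 0.05),
    h = matrix(0, 401, n), z = matrix(0, 401, n), r = matrix(0, 401, n),
    params = net$params, gate_override = NULL, inputs = list(), dt = 0.05,
    record_every = 1L, effective_alpha_z = 0, effective_alpha_r = 0),
    class = "trajectory")
  m <- steady_state_moments(zero_traj)
  expect_equal(m$phi2, 0)
  expect_equal(m$phip2, 9)      # phi'(0)^2 = g_h^2
  expect_equal(m$sz, 0.5)
  short <- zero_traj
  expect_error(steady_state_moments(short, burn_in_fraction = 0.99),
               "100 samples")
})

test_that("chaotic steady state matches the mean-field variance", {
  p <- network_params(800, g_h = 3, seed = 5)
  tr <- simulate_network(make_network(p), t_final = 120, record_every = 4)
  expect_true(is_stationary(tr))
  m <- steady_state_moments(tr)
  sol <- solve_fixed_point(p)
  expect_lt(abs(m$h2 - sol$delta_h) / sol$delta_h, 0.15)
})
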