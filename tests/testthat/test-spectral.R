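test_that("the Jacobian has the documented block structure at the origin", {
  n <- 15
  net <- make_network(network_params(n, g_h = 2.4, seed = 3))
  J <- instantaneous_jacobian(net, list(h = numeric(n), z = numeric(n),
                                        r = numeric(n)))
  hh_expect <- 0.5 * (-diag(n) + net$J_h * (2.4 * 0.5))
  expect_equal(J[1:n, 1:n], hh_expect)
  expect_equal(J[1:n, n + 1:n], matrix(0, n, n))      # D term vanishes
  expect_equal(J[1:n, 2 * n + 1:n], matrix(0, n, n))  # phi(0) = 0
  expect_equal(diag(J[n + 1:n, n + 1:n]), rep(-1, n))
})

test_that("the Jacobian matches central differences of the vector field", {
  n <- 20
  p <- network_params(n, g_h = 1.7, alpha_z = 2, alpha_r = 3, beta_z = 0.3,
                      beta_r = -0.2, beta_h = 0.1, tau_z = 2, tau_r = 1.5,
                      seed = 4)
  net <- make_network(p)
  set.seed(5)
  st <- list(h = rnorm(n), z = rnorm(n), r = rnorm(n))
  J <- instantaneous_jacobian(net, st)
  f <- function(x) {
    h <- x[1:n]; z <- x[n + 1:n]; r <- x[2 * n + 1:n]
    phi <- tanh(1.7 * h + 0.1)
    sz <- 1 / (1 + exp(-2 * z + 0.3)); sr <- 1 / (1 + exp(-3 * r - 0.2))
    c(sz * (-h + net$J_h %*% (phi * sr)),
      (-z + net$J_z %*% phi) / 2,
      (-r + net$J_r %*% phi) / 1.5)
  }
  x0 <- c(st$h, st$z, st$r); eps <- 1e-6
  Jfd <- vapply(1:(3 * n), function(j) {
    e <- numeric(3 * n); e[j] <- eps
    (f(x0 + e) - f(x0 - e)) / (2 * eps)
  }, numeric(3 * n))
  expect_lt(max(abs(J - Jfd)), 1e-5)
})

test_that("pinned gates reduce the h block to the classical Jacobian", {
  n <- 12
  net <- make_network(network_params(n, g_h = 1.5, seed = 6),
                      gate_override = list(z = 1, r = 1))
  set.seed(7); h <- rnorm(n)
  J <- instantaneous_jacobian(net, list(h = h, z = numeric(n), r = numeric(n)))
  phip <- activation_deriv(h, 1.5)
  expect_equal(J[1:n, 1:n], -diag(n) + sweep(net$J_h, 2, phip, `*`))
})

test_that("empirical_spectrum recovers a known spectrum", {
  a <- c(-2, -0.5, 0.3, 1.7)
  expect_equal(sort(Re(empirical_spectrum(diag(a)))), sort(a))
})

test_that("the zero-FP boundary is the predicted circle", {
  # bias-free, alpha_r = 0: |lambda + 1/2| = g_h / 4
  for (g in c(1.2, 2.5, 3)) {
    sc <- spectral_curve(zero_fp_moments(network_params(2, g_h = g)))
    expect_equal(sc$leading_edge, -0.5 + g / 4, tolerance = 1e-8)
    d <- sqrt((do.call(rbind, sc$boundary)$re + 0.5)^2 +
                do.call(rbind, sc$boundary)$im^2)
    expect_lt(max(abs(d - g / 4)), 0.02)  # polyline at grid resolution
    intercept_expect <- if (g / 4 > 0.5) sqrt((g / 4)^2 - 0.25) else 0
    expect_equal(sc$imag_intercept, intercept_expect, tolerance = 1e-6)
  }
  # the leading edge crosses the origin exactly at g_h = 2
  sc2 <- spectral_curve(zero_fp_moments(network_params(2, g_h = 2)))
  expect_lt(abs(sc2$leading_edge), 1e-8)
})

test_that("the instability criterion flips at the threshold, ties stable", {
  expect_false(fp_unstable(zero_fp_moments(network_params(2, g_h = 1.9))))
  expect_true(fp_unstable(zero_fp_moments(network_params(2, g_h = 2.1))))
  expect_false(fp_unstable(zero_fp_moments(network_params(2, g_h = 2))))
})

test_that("instability and a positive leading edge agree on random points", {
  set.seed(31)
  for (i in 1:8) {
    p <- network_params(2, g_h = runif(1, 0.5, 3.5),
                        alpha_r = runif(1, 0, 6), beta_r = runif(1, -1, 1))
    m <- zero_fp_moments(p)
    sc <- spectral_curve(m)
    expect_equal(fp_unstable(m), sc$leading_edge > 0)
  }
})

test_that("the binary-gate disk radius collapses correctly and marks the window", {
  m <- structure(list(phip2 = 3, sz = 0.5, sr2 = 0.25, srp2 = 0, phi2 = 0.4,
                      sz2 = 0.5, z_spec = list(type = "binary", f = 0.5)),
                 class = "state_moments")
  expect_equal(as.numeric(marginal_stability_radius(m)),
               sqrt(3 * 0.5 * 0.25))  # b = 0 collapses to sqrt(a)
  # joint MFT + radius against the adaptive-quadrature oracle
  rho_at <- function(g) {
    p <- network_params(2, g_h = g, alpha_z = Inf)
    as.numeric(marginal_stability_radius(fixed_point_moments(p)))
  }
  rhos <- vapply(c(3, 4.5, 6, 7), rho_at, numeric(1))
  expect_true(all(diff(rhos) > 0))         # continuous growth along the window
  expect_lt(rhos[3], 1)                    # g = 6 still marginal
  expect_gt(rhos[4], 1)                    # g = 7 chaotic
  # oracle cross-check of the radius at g = 6
  d6 <- oracle_delta_h(6)
  phip2 <- oracle_gauss_avg(function(x) (6 / cosh(6 * x)^2)^2, d6)
  expect_equal(rhos[3], sqrt(phip2 / 8), tolerance = 1e-4)
})

test_that("the limiting binary-gate density normalizes and has the right atoms", {
  mu <- limiting_density_infinite_alpha_z(0.5, 0.8, 3)
  expect_equal(mu$weight_zero + mu$weight_minus_one + mu$disk_weight, 1)
  expect_equal(mu$disk_density * pi * mu$disk_radius^2, mu$disk_weight,
               tolerance = 1e-12)
  pure <- limiting_density_infinite_alpha_z(1, 1, 2)
  expect_equal(pure$disk_weight, 1)
  expect_equal(pure$disk_radius, 1)
  frozen <- limiting_density_infinite_alpha_z(0, 0.5, 2)
  expect_equal(frozen$weight_zero, 1)
  expect_error(limiting_density_infinite_alpha_z(1.2, 0.5, 2), "0, 1")
})

test_that("the switchlike gate accumulates the predicted zero-mode cluster", {
  p <- network_params(400, g_h = 3, alpha_z = 100, seed = 3)
  net <- make_network(p)
  tr <- simulate_network(net, t_final = 150, record_every = 4)
  m <- steady_state_moments(tr)
  ev <- empirical_spectrum(instantaneous_jacobian(net, final_state(tr)))
  cluster_frac <- sum(Mod(ev) < 0.05) / p$n_units
  expect_lt(abs(cluster_frac - (1 - m$sz)), 0.05)
})
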