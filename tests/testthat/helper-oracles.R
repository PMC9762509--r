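# Independent oracles used across the test files.

# Gaussian expectation by adaptive quadrature (independent of the package's
# Gauss-Hermite path)
oracle_gauss_avg <- function(f, variance) {
  if (variance == 0) return(f(0))
  s <- sqrt(variance)
  stats::integrate(function(x) f(x) * stats::dnorm(x, 0, s), -Inf, Inf,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

# fixed-point variance of the bias-free mean-field closure via the oracle
# integrator (damped iteration written independently of solve_fixed_point)
oracle_delta_h <- function(g_h, alpha_r = 0, tol = 1e-12) {
  d <- 1
  for (i in 1:50000) {
    phi2 <- oracle_gauss_avg(function(x) tanh(g_h * x)^2, d)
    sr2 <- oracle_gauss_avg(function(x) 1 / (1 + exp(-alpha_r * x))^2, phi2)
    d2 <- 0.5 * d + 0.5 * phi2 * sr2
    if (abs(d2 - d) < tol) break
    d <- d2
  }
  d
}

# classical additive RNN xdot = -x + J phi(x), plain-R RK4 (oracle for the
# pinned-gate limit of the compiled integrator)
oracle_classical_rk4 <- function(J, g_h, x0, t_final, dt) {
  f <- function(x) -x + J %*% tanh(g_h * x)
  x <- x0
  for (i in seq_len(round(t_final / dt))) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  drop(x)
}

# small canonical parameter sets
params_tiny <- function(n = 20, ...) network_params(n_units = n, g_h = 1.5,
                                                    seed = 42, ...)
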