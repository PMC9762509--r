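# Lyapunov analysis: full spectra by tangent-space QR reorthonormalization,
# Kaplan-Yorke dimension, two-time correlators of the steady state, and the
# dynamical mean-field prediction for the maximal Lyapunov exponent.

#' Lyapunov spectrum by the Benettin/QR method
#'
#' Evolves `k` tangent vectors with the instantaneous Jacobian alongside the
#' trajectory (both with fixed-step RK4), reorthonormalizes every
#' `reorth_interval` time units, and averages the log diagonal of the R
#' factors after `t_transient`.  Exponents are per unit time, sorted
#' nonincreasing.
#'
#' @param net a [make_network()] network.
#' @param k number of exponents (k <= 3N).
#' @param t_total,t_transient total and discarded time.
#' @param reorth_interval time between QR reorthonormalizations.
#' @param dt integration step.
#' @param inputs list of [input_protocol()] objects.
#' @param init,init_scale,init_seed initial state control as in
#'   [simulate_network()].
#' @param infinite_gate,surrogate_alpha infinite-gain handling as in
#'   [simulate_network()].
#' @return An object of class `"lyapunov_result"`: `exponents`,
#'   `ky_dimension` (NA when more exponents would be needed), `mean_trace`
#'   (time-averaged Jacobian trace, for sum-rule checks), the final state and
#'   the run settings.
#' @export
lyapunov_spectrum <- function(net, k = 50L, t_total = 2000, t_transient = 200,
                              reorth_interval = 1.0, dt = 0.05,
                              inputs = list(), init = NULL, init_scale = 0.1,
                              init_seed = NULL,
                              infinite_gate = c("surrogate", "heaviside"),
                              surrogate_alpha = 100) {
  stopifnot(inherits(net, "gated_network"))
  p <- net$params; n <- p$n_units
  k <- as.integer(k)
  if (k < 1 || k > 3 * n) stop("need 1 <= k <= 3N", call. = FALSE)
  if (t_total <= t_transient) stop("need t_total > t_transient", call. = FALSE)
  infinite_gate <- match.arg(infinite_gate)
  seed <- if (is.null(init_seed)) p$seed else init_seed
  init <- resolve_init(init, n, init_scale, seed)
  inp <- pack_inputs(inputs, n)
  par <- cpp_par(p, net$gate_override, infinite_gate, surrogate_alpha)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(substream_seed(seed, "tangent"))
  V0 <- matrix(rnorm(3 * n * k), 3 * n, k)
  out <- lyapunov_cpp(net$J_h, net$J_z, net$J_r, par,
                      init$h, init$z, init$r, k, dt, t_total, t_transient,
                      reorth_interval, inp$ivecs, inp$target, inp$t_on,
                      inp$t_off, V0)
  expo <- as.numeric(out$exponents)
  ky <- tryCatch(kaplan_yorke(expo), error = function(e) NA_real_)
  structure(list(exponents = expo, k = k, ky_dimension = ky,
                 t_total = t_total, t_transient = t_transient,
                 reorth_interval = reorth_interval, dt = dt,
                 mean_trace = out$mean_trace,
                 final = list(h = as.numeric(out$final_h),
                              z = as.numeric(out$final_z),
                              r = as.numeric(out$final_r)),
                 params = p),
            class = "lyapunov_result")
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("Lyapunov spectrum (k = %d, T = %g):\n", x$k, x$t_total))
  cat(sprintf("  lambda_max = %.5f, KY dimension = %s\n", x$exponents[1],
              if (is.na(x$ky_dimension)) "NA" else format(x$ky_dimension)))
  invisible(x)
}

#' Maximal Lyapunov exponent
#'
#' Single-tangent-vector version of [lyapunov_spectrum()].
#'
#' @inheritParams lyapunov_spectrum
#' @return numeric scalar.
#' @export
estimate_lambda_max <- function(net, t_total = 300, t_transient = 50, ...) {
  lyapunov_spectrum(net, k = 1L, t_total = t_total,
                    t_transient = t_transient, ...)$exponents[1]
}

#' Kaplan-Yorke attractor dimension
#'
#' \eqn{D_A = M + \sum_{i \le M}\lambda_i / |\lambda_{M+1}|} with M the
#' largest j whose partial sum of ordered exponents is nonnegative.  Returns
#' 0 when the largest exponent is negative.
#'
#' @param exponents numeric vector, sorted nonincreasing.
#' @return nonnegative scalar.
#' @examples
#' kaplan_yorke(c(0.5, -1))    # 1.5
#' kaplan_yorke(c(-0.1, -0.2)) # 0
#' @export
kaplan_yorke <- function(exponents) {
  if (is.unsorted(rev(exponents), strictly = FALSE))
    stop("exponents must be sorted nonincreasing", call. = FALSE)
  if (exponents[1] < 0) return(0)
  cs <- cumsum(exponents)
  M <- max(which(cs >= 0))
  if (M + 1 > length(exponents))
    stop("all partial sums are nonnegative; compute more exponents",
         call. = FALSE)
  M + cs[M] / abs(exponents[M + 1])
}

#' Two-time correlation functions of the steady state
#'
#' Estimates the population- and time-averaged correlators
#' \eqn{C_x(\tau) = \langle x_i(t) x_i(t+\tau)\rangle} over the post-burn-in
#' window, for \eqn{x \in \{h, \phi, \phi', \sigma_z, \sigma_z', \sigma_r,
#' \phi\sigma_r\}}.  Lags are multiples of the trajectory's recording
#' interval.  By stationarity the correlators are even in \eqn{\tau}; only
#' the nonnegative lags are stored.
#'
#' @param traj a [simulate_network()] trajectory.
#' @param max_lag largest lag (time units).
#' @param burn_in fraction of the run discarded.
#' @return An object of class `"correlator_set"` with fields `lags`, `C_h`,
#'   `C_phi`, `C_phip`, `C_sz`, `C_szp`, `C_sr`, `C_phisr`, `window`,
#'   `stationary`.
#' @export
measure_correlators <- function(traj, max_lag = 20, burn_in = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  dtau <- traj$dt * traj$record_every
  nlag <- floor(max_lag / dtau)
  nt <- length(traj$times)
  keep <- seq(floor(nt * burn_in) + 1, nt)
  if (length(keep) < 10 * nlag)
    stop("post-burn-in segment shorter than 10 x max_lag; run longer",
         call. = FALSE)
  p <- traj$params; ov <- traj$gate_override
  h <- traj$h[keep, , drop = FALSE]
  z <- traj$z[keep, , drop = FALSE]
  r <- traj$r[keep, , drop = FALSE]
  az <- traj$effective_alpha_z; ar <- traj$effective_alpha_r
  sig <- list(
    h = h,
    phi = activation(h, p$g_h, p$beta_h),
    phip = activation_deriv(h, p$g_h, p$beta_h),
    sz = if (is.null(ov$z)) gate_value(z, az, p$beta_z) else array(ov$z, dim(z)),
    szp = if (is.null(ov$z)) gate_deriv(z, az, p$beta_z) else array(0, dim(z)),
    sr = if (is.null(ov$r)) gate_value(r, ar, p$beta_r) else array(ov$r, dim(r)))
  sig$phisr <- sig$phi * sig$sr

  Tn <- nrow(h)
  corr <- function(X) {
    vapply(0:nlag, function(l) {
      a <- X[seq_len(Tn - l), , drop = FALSE]
      b <- X[seq_len(Tn - l) + l, , drop = FALSE]
      mean(a * b)
    }, numeric(1))
  }
  structure(list(lags = (0:nlag) * dtau,
                 C_h = corr(sig$h), C_phi = corr(sig$phi),
                 C_phip = corr(sig$phip), C_sz = corr(sig$sz),
                 C_szp = corr(sig$szp), C_sr = corr(sig$sr),
                 C_phisr = corr(sig$phisr),
                 window = diff(range(traj$times[keep])),
                 stationary = is_stationary(traj), params = p),
            class = "correlator_set")
}

#' DMFT prediction for the maximal Lyapunov exponent
#'
#' Solves the mean-field eigenproblem for the growth rate \eqn{\kappa} of an
#' infinitesimal perturbation,
#' \deqn{[(\langle\sigma_z\rangle+\kappa)^2 - \partial_\tau^2]\chi(\tau) =
#'   \langle\sigma_z\rangle^2\, C_{\phi'}(\tau) C_{\sigma_r}(\tau)\,
#'   \chi(\tau),}
#' on the measured lag grid, with \eqn{-\partial_\tau^2} represented by
#' second differences and Dirichlet conditions at the window ends.  The
#' closure \eqn{\partial C_{\phi\sigma_r}/\partial C_h =
#' C_{\phi'}C_{\sigma_r}} treats \eqn{(h, r)} as jointly Gaussian with
#' vanishing on-site cross-covariance (independent coupling matrices) and
#' applies Price's theorem for the h-variation; it is valid at
#' `alpha_z = 0`, where the update gate is the constant
#' \eqn{\sigma_z(0)} and the h field is Gaussian.  For `alpha_z != 0` the
#' h distribution is non-Gaussian and the closure fails; the function
#' refuses with an error.
#'
#' Because the \eqn{\kappa}-dependence enters only through the scalar factor
#' \eqn{(\langle\sigma_z\rangle+\kappa)^2}, the quadratic eigenproblem
#' reduces exactly to \eqn{\kappa_{\max} = -\langle\sigma_z\rangle +
#' \sqrt{\ell_{\max}}} with \eqn{\ell_{\max}} the largest eigenvalue of the
#' symmetric operator \eqn{\partial_\tau^2 +
#' \langle\sigma_z\rangle^2 C_{\phi'}C_{\sigma_r}} (the companion
#' linearization collapses to this closed form).  When \eqn{\ell_{\max} < 0}
#' all modes are oscillatory-decaying and the real part
#' \eqn{-\langle\sigma_z\rangle} is returned.
#'
#' @param correlators a [measure_correlators()] result.
#' @param params the [network_params()] the correlators were measured at.
#' @return `kappa_max`, the DMFT maximal Lyapunov exponent.
#' @export
dmft_lambda_max <- function(correlators, params) {
  stopifnot(inherits(correlators, "correlator_set"))
  if (params$alpha_z != 0)
    stop(paste("the Gaussian/Price closure for the DMFT eigenproblem is only",
               "valid at alpha_z = 0; the h distribution is strongly",
               "non-Gaussian for switchlike update gates"), call. = FALSE)
  sz0 <- gate_value(0, 0, params$beta_z)  # constant gate at alpha_z = 0
  lag <- correlators$lags
  dtau <- lag[2] - lag[1]
  # symmetric grid tau in [-T, T]; correlators are even
  q_half <- sz0^2 * correlators$C_phip * correlators$C_sr
  q <- c(rev(q_half[-1]), q_half)
  n <- length(q)
  # operator d^2/dtau^2 + q(tau), Dirichlet at the ends
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- -2 / dtau^2 + q
  A[cbind(1:(n - 1), 2:n)] <- 1 / dtau^2
  A[cbind(2:n, 1:(n - 1))] <- 1 / dtau^2
  ell <- eigen(A, symmetric = TRUE, only.values = TRUE)$values[1]
  if (ell >= 0) -sz0 + sqrt(ell) else -sz0
}
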