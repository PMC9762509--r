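#' Parameters of a gated recurrent network
#'
#' Bundles the scalar model parameters of the gated RNN: the activation gain
#' and bias, the two gate gains and biases, the gate time constants (in units
#' of the `h` time constant, which is 1), the network size and the seed used
#' to draw couplings.
#'
#' The activation is \eqn{\phi(x) = \tanh(g_h x + \beta_h)} and each gate is
#' the sigmoid \eqn{\sigma(x) = [1 + \exp(-\alpha x + \beta)]^{-1}}.  Gate
#' gains may be `Inf`, in which case the gate is the Heaviside step (see
#' [gate_value()]); this is an explicit flag, never a large float.
#'
#' @param n_units number of units N (at least 2).
#' @param g_h activation gain (nonnegative).
#' @param alpha_z,alpha_r update/output gate gains; nonnegative or `Inf`.
#' @param beta_h,beta_z,beta_r biases of the activation and the two gates.
#' @param tau_z,tau_r gate time constants (positive).
#' @param seed integer seed from which coupling matrices and default initial
#'   conditions are drawn (via named substreams).
#'
#' @return An object of class `"network_params"`.
#' @examples
#' p <- network_params(n_units = 100, g_h = 3)
#' p
#' @export
network_params <- function(n_units, g_h, alpha_z = 0, alpha_r = 0,
                           beta_h = 0, beta_z = 0, beta_r = 0,
                           tau_z = 1, tau_r = 1, seed = 1L) {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 2)
    stop("`n_units` must be an integer >= 2", call. = FALSE)
  for (nm in c("g_h", "alpha_z", "alpha_r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop(sprintf("`%s` must be a single nonnegative number", nm), call. = FALSE)
  }
  if (is.infinite(g_h)) stop("`g_h` must be finite", call. = FALSE)
  for (nm in c("beta_h", "beta_z", "beta_r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  if (!is.numeric(tau_z) || tau_z <= 0 || !is.numeric(tau_r) || tau_r <= 0)
    stop("`tau_z` and `tau_r` must be positive", call. = FALSE)
  structure(list(n_units = n_units, g_h = g_h,
                 alpha_z = alpha_z, alpha_r = alpha_r,
                 beta_h = beta_h, beta_z = beta_z, beta_r = beta_r,
                 tau_z = tau_z, tau_r = tau_r, seed = as.integer(seed)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "Inf" else format(v)
  cat("Gated RNN parameters\n")
  cat(sprintf("  N = %d, seed = %d\n", x$n_units, x$seed))
  cat(sprintf("  activation: g_h = %s, beta_h = %s\n", fmt(x$g_h), fmt(x$beta_h)))
  cat(sprintf("  update gate: alpha_z = %s, beta_z = %s, tau_z = %s\n",
              fmt(x$alpha_z), fmt(x$beta_z), fmt(x$tau_z)))
  cat(sprintf("  output gate: alpha_r = %s, beta_r = %s, tau_r = %s\n",
              fmt(x$alpha_r), fmt(x$beta_r), fmt(x$tau_r)))
  invisible(x)
}

# shallow update helper used throughout the phase-diagram code
update_params <- function(params, ...) {
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(params)))
  do.call(network_params, modifyList(unclass(params), dots))
}
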