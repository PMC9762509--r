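#' Sigmoidal gate function
#'
#' Evaluates the gate \eqn{\sigma(x) = [1 + \exp(-\alpha x + \beta)]^{-1}}
#' elementwise.  For `alpha = Inf` the gate is the Heaviside step with
#' threshold at `x = 0`: 1 for `x > 0`, 0 for `x < 0`, and the finite-alpha
#' value \eqn{1/(1+e^{\beta})} exactly at 0 (the deterministic tie rule; this
#' is 1/2 when `beta = 0`).
#'
#' @param x numeric vector.
#' @param alpha gate gain, nonnegative or `Inf`.
#' @param beta gate bias.
#' @return numeric vector of values in \[0, 1\].
#' @examples
#' gate_value(0, alpha = 5, beta = 0)       # 0.5
#' gate_value(c(-1, 0, 1), Inf, 0)          # 0, 0.5, 1
#' @export
gate_value <- function(x, alpha, beta = 0) {
  if (is.infinite(alpha)) {
    out <- as.numeric(x > 0)
    out[x == 0] <- 1 / (1 + exp(beta))
    return(out)
  }
  1 / (1 + exp(-alpha * x + beta))
}

#' Derivative of the gate function
#'
#' \eqn{\sigma'(x) = \alpha \sigma(x)(1-\sigma(x))}.  For `alpha = Inf` the
#' derivative is taken to be 0 everywhere (its almost-everywhere value).
#'
#' @inheritParams gate_value
#' @return numeric vector.
#' @export
gate_deriv <- function(x, alpha, beta = 0) {
  if (is.infinite(alpha)) return(numeric(length(x)) + 0 * x)
  s <- gate_value(x, alpha, beta)
  alpha * s * (1 - s)
}

#' Activation function and its derivative
#'
#' \eqn{\phi(x) = \tanh(g_h x + \beta_h)} and
#' \eqn{\phi'(x) = g_h [1 - \phi(x)^2]}.
#'
#' @param x numeric vector.
#' @param g_h activation gain.
#' @param beta_h activation bias.
#' @return numeric vector.
#' @export
activation <- function(x, g_h, beta_h = 0) tanh(g_h * x + beta_h)

#' @rdname activation
#' @export
activation_deriv <- function(x, g_h, beta_h = 0) {
  t <- tanh(g_h * x + beta_h)
  g_h * (1 - t^2)
}
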