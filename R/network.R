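#' Realize a gated network from parameters
#'
#' Draws the three independent coupling matrices `J_h`, `J_z`, `J_r` with
#' i.i.d. Gaussian entries of mean 0 and variance `1/N`, so that the input to
#' each unit stays O(1) as N grows.  The draw is reproducible: it uses the
#' `couplings` substream of `params$seed`, and two calls with the same
#' parameters give bit-identical matrices.
#'
#' @param params a [network_params()] object.
#' @param gate_override optional named list pinning gates to constants, e.g.
#'   `list(z = 1, r = 1)` recovers the classical additive RNN
#'   \eqn{\dot x = -x + J\phi(x)}.  Pinned gates have zero derivative.
#' @return An object of class `"gated_network"` with elements `params`,
#'   `J_h`, `J_z`, `J_r` and `gate_override`.
#' @examples
#' net <- make_network(network_params(50, g_h = 2, seed = 7))
#' dim(net$J_h)
#' @export
make_network <- function(params, gate_override = NULL) {
  stopifnot(inherits(params, "network_params"))
  if (!is.null(gate_override)) {
    if (!all(names(gate_override) %in% c("z", "r")))
      stop("gate_override names must be in c('z', 'r')", call. = FALSE)
    ok <- vapply(gate_override, function(v)
      is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1, logical(1))
    if (!all(ok)) stop("gate_override values must be constants in [0, 1]",
                       call. = FALSE)
  }
  n <- params$n_units
  sd <- sqrt(1 / n)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(substream_seed(params$seed, "couplings"))
  J_h <- matrix(rnorm(n * n, 0, sd), n, n)
  J_z <- matrix(rnorm(n * n, 0, sd), n, n)
  J_r <- matrix(rnorm(n * n, 0, sd), n, n)
  structure(list(params = params, J_h = J_h, J_z = J_z, J_r = J_r,
                 gate_override = gate_override),
            class = "gated_network")
}

#' @export
print.gated_network <- function(x, ...) {
  cat(sprintf("Gated RNN, N = %d (couplings ~ N(0, 1/N))\n", x$params$n_units))
  if (!is.null(x$gate_override))
    cat("  pinned gates:",
        paste(sprintf("sigma_%s = %g", names(x$gate_override),
                      unlist(x$gate_override)), collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

# save/restore the global RNG state so that seeded draws inside the package
# do not perturb the caller's stream
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
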