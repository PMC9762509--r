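#' Canonical test networks, one per dynamical regime
#'
#' A frozen set of parameter points used throughout the test suite and the
#' worked examples, one in each region of the bias-free phase diagram plus
#' the marginally stable surrogate, realized at a requested size.  Checksums
#' of the serialized coupling matrices are recorded so that test
#' infrastructure can detect drift in the generator.
#'
#' @param seed root seed.
#' @param n_units network size (canonical sizes: 20, 100, 600).
#' @return named list of `"gated_network"` objects (`region1`, `region2`,
#'   `region3`, `region4`, `marginal`) with attribute `"checksums"` (MD5 of
#'   each network's serialized couplings).
#' @export
fixture_suite <- function(seed = 1L, n_units = 100L) {
  pts <- list(
    region1  = list(g_h = 1.2, alpha_r = 1,   alpha_z = 0),
    region2  = list(g_h = 1.9, alpha_r = 7,   alpha_z = 0),
    region3  = list(g_h = 1.9, alpha_r = 13,  alpha_z = 0),
    region4  = list(g_h = 3,   alpha_r = 0,   alpha_z = 0),
    marginal = list(g_h = 3,   alpha_r = 2.5, alpha_z = 100))
  nets <- lapply(pts, function(pt) {
    make_network(network_params(n_units, g_h = pt$g_h, alpha_r = pt$alpha_r,
                                alpha_z = pt$alpha_z, seed = seed))
  })
  sums <- vapply(nets, function(net) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(list(net$J_h, net$J_z, net$J_r), f, version = 3, compress = FALSE)
    unname(tools::md5sum(f))
  }, character(1))
  attr(nets, "checksums") <- sums
  nets
}
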