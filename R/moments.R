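# Moment sets: the equal-time averages that enter the random-matrix spectral
# curve.  They can be measured from a trajectory (concentration of measure
# replaces population averages by distribution averages at large N) or
# evaluated on the Gaussian fixed-point distributions from the MFT.
#
# The z-distribution is carried along ("z_spec") because the spectral curve
# needs the full average <sigma_z^2 / |lambda + sigma_z|^2>, not just moments:
#   - gaussian: z ~ N(mean, delta), gate (alpha_z, beta_z)
#   - binary:   sigma_z in {0, 1} with P(1) = f (the alpha_z = Inf limit)
#   - point:    sigma_z identically s0 (zero fixed point, or pinned gate)
#   - empirical: samples of z from a trajectory, gate (alpha_z, beta_z)

new_state_moments <- function(vals, z_spec, params = NULL) {
  structure(c(vals, list(z_spec = z_spec, params = params)),
            class = "state_moments")
}

#' @export
print.state_moments <- function(x, ...) {
  cat("State moments:\n")
  for (nm in c("phi2", "phip2", "sr2", "srp2", "sz", "sz2"))
    cat(sprintf("  <%s> = %.6g\n", nm, x[[nm]]))
  cat(sprintf("  z distribution: %s\n", x$z_spec$type))
  invisible(x)
}

#' Time- and population-averaged moments of a steady state
#'
#' Averages \eqn{\phi^2, \phi'^2, \sigma_r^2, \sigma_r'^2, \sigma_z,
#' \sigma_z^2, h^2, z^2, r^2} over the post-burn-in window of a trajectory.
#' Gate values use the effective gains of the integration (i.e. the surrogate
#' gain if an infinite gate was integrated smoothly) and respect pinned gates.
#' A subsample of z values is kept so that spectral-curve z-averages can be
#' taken against the empirical distribution.
#'
#' @param traj a [simulate_network()] trajectory.
#' @param burn_in_fraction fraction of the run discarded as transient.
#' @param max_z_samples size cap for the retained z subsample.
#' @return A `"state_moments"` object.
#' @export
steady_state_moments <- function(traj, burn_in_fraction = 0.5,
                                 max_z_samples = 20000L) {
  stopifnot(inherits(traj, "trajectory"))
  nt <- length(traj$times)
  keep <- seq(floor(nt * burn_in_fraction) + 1, nt)
  if (length(keep) < 100)
    stop("fewer than 100 samples remain after burn-in; run longer or lower burn_in_fraction",
         call. = FALSE)
  p <- traj$params
  ov <- traj$gate_override
  h <- traj$h[keep, , drop = FALSE]
  z <- traj$z[keep, , drop = FALSE]
  r <- traj$r[keep, , drop = FALSE]
  az <- traj$effective_alpha_z; ar <- traj$effective_alpha_r

  phi <- activation(h, p$g_h, p$beta_h)
  phip <- activation_deriv(h, p$g_h, p$beta_h)
  if (is.null(ov$r)) {
    sr <- gate_value(r, ar, p$beta_r); srp <- gate_deriv(r, ar, p$beta_r)
  } else {
    sr <- array(ov$r, dim(r)); srp <- array(0, dim(r))
  }
  if (is.null(ov$z)) {
    sz <- gate_value(z, az, p$beta_z)
  } else {
    sz <- array(ov$z, dim(z))
  }

  zs <- as.numeric(z)
  if (length(zs) > max_z_samples)
    zs <- zs[round(seq(1, length(zs), length.out = max_z_samples))]
  z_spec <- if (is.null(ov$z)) {
    list(type = "empirical", samples = zs, alpha_z = az, beta_z = p$beta_z)
  } else {
    list(type = "point", value = ov$z)
  }
  new_state_moments(
    list(phi2 = mean(phi^2), phip2 = mean(phip^2),
         sr2 = mean(sr^2), srp2 = mean(srp^2),
         sz = mean(sz), sz2 = mean(sz^2),
         h2 = mean(h^2), z2 = mean(z^2), r2 = mean(r^2)),
    z_spec, params = p)
}

#' Moments on the Gaussian fixed-point distributions
#'
#' Evaluates the spectral-curve moment set on the mean-field fixed point:
#' all averages are over \eqn{(h, z, r) \sim N(0, \Delta_{h,z,r})}.  With
#' `alpha_z = Inf` the z-gate is binary and the z-distribution collapses to
#' the two-point law with \eqn{P(\sigma_z = 1) = P(z > 0)}.
#'
#' @param params a [network_params()] object.
#' @param solution an `"mft_solution"`; defaults to the nonzero branch at
#'   these parameters.
#' @param nodes Gauss-Hermite node count.
#' @return A `"state_moments"` object.
#' @export
fixed_point_moments <- function(params, solution = NULL, nodes = 201L) {
  if (is.null(solution)) solution <- solve_fixed_point(params, nodes = nodes)
  dh <- solution$delta_h; dz <- solution$delta_z; dr <- solution$delta_r
  dphi <- if (is.null(solution$delta_phi_arg)) dh else solution$delta_phi_arg
  m <- mft_moment_set(params, dphi, dz, dr, nodes = nodes)
  z_spec <- if (is.infinite(params$alpha_z)) {
    if (dz > 0) list(type = "binary", f = stats::pnorm(0, 0, sqrt(dz),
                                                       lower.tail = FALSE))
    else list(type = "point", value = gate_value(0, Inf, params$beta_z))
  } else if (dz > 0) {
    list(type = "gaussian", delta = dz, mean = 0,
         alpha_z = params$alpha_z, beta_z = params$beta_z)
  } else {
    list(type = "point", value = gate_value(0, params$alpha_z, params$beta_z))
  }
  new_state_moments(
    c(m, list(h2 = dh, z2 = dz, r2 = dr)), z_spec, params = params)
}

#' @rdname fixed_point_moments
#' @export
zero_fp_moments <- function(params, nodes = 201L) {
  if (params$beta_h != 0)
    stop("the zero fixed point only exists with beta_h = 0", call. = FALSE)
  fixed_point_moments(params,
                      solve_fixed_point(params, init_branch = "zero"),
                      nodes = nodes)
}
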