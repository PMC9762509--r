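# Random-matrix theory of the instantaneous Jacobian.
#
# The 3N x 3N Jacobian of the gated dynamics has the block structure
#   [ [sz](-1 + J^h [phi' sr])    D                [sz] J^h [phi sr'] ]
#   [ J^z [phi'] / tau_z          -1/tau_z         0                  ]
#   [ J^r [phi'] / tau_r          0                -1/tau_r           ]
# with D = diag(sz'(z) (-h + J^h (phi sr))), which vanishes at fixed points.
# The support boundary of its spectrum is predicted by the spectral-curve
# equation
#   <phi'^2> ( <sr^2> + <phi^2><sr'^2> / |1 + tau_r lambda|^2 )
#            * < sz^2 / |lambda + sz|^2 >_z  =  1.

#' Instantaneous Jacobian of the gated dynamics
#'
#' Assembles the dense 3N-by-3N Jacobian at a state.  The state may be a
#' `list(h, z, r)` (e.g. from [final_state()]) or a numeric vector of length
#' 3N ordered (h, z, r).  Infinite gate gains give the Heaviside gate with
#' zero derivative; pinned gates are constants with zero derivative.
#'
#' @param net a [make_network()] network.
#' @param state state at which to linearize.
#' @return a 3N x 3N numeric matrix.
#' @export
instantaneous_jacobian <- function(net, state) {
  stopifnot(inherits(net, "gated_network"))
  p <- net$params; n <- p$n_units
  if (is.numeric(state)) {
    if (length(state) != 3 * n) stop("state must have length 3N", call. = FALSE)
    state <- list(h = state[1:n], z = state[n + 1:n], r = state[2 * n + 1:n])
  }
  stopifnot(length(state$h) == n, length(state$z) == n, length(state$r) == n)
  ov <- net$gate_override
  phi <- activation(state$h, p$g_h, p$beta_h)
  phip <- activation_deriv(state$h, p$g_h, p$beta_h)
  if (is.null(ov$r)) {
    sr <- gate_value(state$r, p$alpha_r, p$beta_r)
    srp <- gate_deriv(state$r, p$alpha_r, p$beta_r)
  } else { sr <- rep(ov$r, n); srp <- rep(0, n) }
  if (is.null(ov$z)) {
    sz <- gate_value(state$z, p$alpha_z, p$beta_z)
    szp <- gate_deriv(state$z, p$alpha_z, p$beta_z)
  } else { sz <- rep(ov$z, n); szp <- rep(0, n) }

  colscale <- function(M, v) sweep(M, 2, v, `*`)
  hh <- sz * colscale(net$J_h, phip * sr); diag(hh) <- diag(hh) - sz
  Dvec <- szp * (-state$h + drop(net$J_h %*% (phi * sr)))
  hr <- sz * colscale(net$J_h, phi * srp)
  zh <- colscale(net$J_z, phip) / p$tau_z
  rh <- colscale(net$J_r, phip) / p$tau_r
  J <- matrix(0, 3 * n, 3 * n)
  i1 <- 1:n; i2 <- n + 1:n; i3 <- 2 * n + 1:n
  J[i1, i1] <- hh
  J[cbind(i1, i2)] <- Dvec
  J[i1, i3] <- hr
  J[i2, i1] <- zh
  J[cbind(i2, i2)] <- -1 / p$tau_z
  J[i3, i1] <- rh
  J[cbind(i3, i3)] <- -1 / p$tau_r
  J
}

#' Eigenvalues of a Jacobian
#'
#' @param jacobian square numeric matrix.
#' @return complex vector of all eigenvalues (unsorted beyond LAPACK order).
#' @export
empirical_spectrum <- function(jacobian) {
  if (any(!is.finite(jacobian))) stop("non-finite Jacobian", call. = FALSE)
  eigen(jacobian, only.values = TRUE)$values
}

# <sigma_z^2 / |lambda + sigma_z|^2> over the z-distribution, vectorized in
# lambda.  For binary gates only the sigma_z = 1 atom contributes.
z_average_sz2 <- function(z_spec, lambda, nodes = 201L) {
  switch(z_spec$type,
    point = {
      s0 <- z_spec$value
      s0^2 / Mod(lambda + s0)^2
    },
    binary = z_spec$f / Mod(lambda + 1)^2,
    gaussian = {
      q <- gh_nodes(nodes)
      zi <- (if (is.null(z_spec$mean)) 0 else z_spec$mean) +
        sqrt(2 * z_spec$delta) * q$x
      si <- gate_value(zi, z_spec$alpha_z, z_spec$beta_z)
      out <- 0
      for (j in seq_along(zi))
        out <- out + q$w[j] * si[j]^2 / Mod(lambda + si[j])^2
      out / sqrt(pi)
    },
    empirical = {
      si <- gate_value(z_spec$samples, z_spec$alpha_z, z_spec$beta_z)
      # bin the gate values for speed; they live in [0, 1]
      br <- seq(0, 1, length.out = 402)
      cnt <- tabulate(findInterval(si, br, all.inside = TRUE), 401)
      mid <- (br[-1] + br[-402]) / 2
      use <- cnt > 0
      out <- 0
      for (j in which(use))
        out <- out + cnt[j] * mid[j]^2 / Mod(lambda + mid[j])^2
      out / sum(cnt)
    },
    stop("unknown z_spec type"))
}

spectral_curve_value <- function(moments, lambda, tau_r = 1, nodes = 201L) {
  m <- moments
  gate_term <- if (m$phi2 * m$srp2 > 0)
    m$phi2 * m$srp2 / Mod(1 + tau_r * lambda)^2 else 0
  m$phip2 * (m$sr2 + gate_term) *
    z_average_sz2(m$z_spec, lambda, nodes = nodes) - 1
}

#' Predicted boundary of the Jacobian spectrum
#'
#' Traces the zero-level set of the spectral-curve equation on a complex grid
#' and reports the leading edge (largest real part on the boundary) and the
#' intercept of the boundary on the imaginary axis.  The leading edge and
#' intercept are refined by bisection to ~1e-10; the polyline itself has grid
#' resolution.  The imaginary grid is chosen to avoid the real segment
#' \eqn{[-1, 0]} where the z-average has poles at \eqn{-\sigma_z}.
#'
#' @param moments a `"state_moments"` object ([steady_state_moments()] or
#'   [fixed_point_moments()]).
#' @param tau_r output-gate time constant entering the curve.
#' @param re_lim,im_lim real/imaginary extent of the tracing grid.
#' @param n_grid grid points per axis (default 600).
#' @param nodes Gauss-Hermite node count for Gaussian z-averages.
#' @return An object of class `"spectral_result"`: `boundary` (list of
#'   closed polylines as data frames with columns `re`, `im`),
#'   `leading_edge`, `imag_intercept`, and the moment snapshot.
#' @export
spectral_curve <- function(moments, tau_r = 1, re_lim = c(-2.5, 2.5),
                           im_lim = c(-2.5, 2.5), n_grid = 600L,
                           nodes = 201L) {
  stopifnot(inherits(moments, "state_moments"))
  G <- function(lam) spectral_curve_value(moments, lam, tau_r, nodes)
  re <- seq(re_lim[1], re_lim[2], length.out = n_grid)
  im <- seq(im_lim[1], im_lim[2], length.out = n_grid)
  if (any(im == 0)) im <- im + diff(im_lim) / (2 * n_grid * 7)  # dodge poles
  lam <- outer(re, im, function(x, y) complex(real = x, imaginary = y))
  gv <- matrix(G(as.vector(lam)), n_grid, n_grid)
  cl <- contourLines(re, im, gv, levels = 0)
  boundary <- lapply(cl, function(s) data.frame(re = s$x, im = s$y))

  leading_edge <- if (length(boundary) == 0) NA_real_ else {
    if (moments$z_spec$type %in% c("point", "binary")) {
      pole <- if (moments$z_spec$type == "point") -moments$z_spec$value else -1
      hi <- max(re_lim[2], 1)
      while (G(complex(real = hi)) > 0 && hi < 128) hi <- hi * 2
      bisect_root(function(x) G(complex(real = x)), pole + 1e-9, hi)
    } else {
      # refine the max-Re vertex along the real direction at fixed Im
      v <- do.call(rbind, boundary)
      i <- which.max(v$re)
      dx <- diff(re[1:2])
      root <- tryCatch(
        bisect_root(function(x) G(complex(real = x, imaginary = v$im[i])),
                    v$re[i] - 2 * dx, min(v$re[i] + 2 * dx, re_lim[2])),
        error = function(e) v$re[i])
      root
    }
  }

  imag_intercept <- local({
    ys <- seq(1e-6, im_lim[2], length.out = 2001)
    gy <- G(complex(real = 0, imaginary = ys))
    sgn <- which(gy[-1] * gy[-length(gy)] < 0)
    if (!length(sgn)) 0 else {
      j <- max(sgn)
      bisect_root(function(y) G(complex(real = 0, imaginary = y)),
                  ys[j], ys[j + 1])
    }
  })

  structure(list(boundary = boundary, leading_edge = leading_edge,
                 imag_intercept = imag_intercept, moments = moments,
                 tau_r = tau_r, re_lim = re_lim, im_lim = im_lim,
                 n_grid = n_grid),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("Spectral curve: %d boundary component(s)\n", length(x$boundary)))
  cat(sprintf("  leading edge  = %.6g\n", x$leading_edge))
  cat(sprintf("  imag intercept = %.6g\n", x$imag_intercept))
  invisible(x)
}

bisect_root <- function(f, lo, hi, tol = 1e-10, maxit = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no sign change in bracket", call. = FALSE)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2; fm <- f(mid)
    if (fm * flo <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Fixed-point instability criterion
#'
#' A mean-field fixed point is unstable when the leading edge of its spectral
#' curve crosses the origin, i.e. when
#' \eqn{\langle\phi'^2\rangle(\langle\phi^2\rangle\langle\sigma_r'^2\rangle +
#' \langle\sigma_r^2\rangle) > 1}.  Equality is classified stable (the
#' transition point itself is measure-zero; tests need a deterministic rule).
#'
#' @param moments a `"state_moments"` object at the fixed point.
#' @return logical.
#' @export
fp_unstable <- function(moments) {
  moments$phip2 * (moments$phi2 * moments$srp2 + moments$sr2) > 1
}

#' Disk radius of the binary-gate spectrum and marginal stability
#'
#' In the switchlike update-gate limit (`alpha_z = Inf`) the Jacobian
#' spectrum splits into an extensive set of exact zero modes and a disk
#' centered at \eqn{\lambda = -1} of radius
#' \eqn{\rho = \sqrt{a/2 + \sqrt{4b + a^2}/2}} with
#' \eqn{a = \langle\phi'^2\rangle\langle\sigma_z\rangle\langle\sigma_r^2\rangle}
#' and \eqn{b = \langle\phi'^2\rangle\langle\sigma_z\rangle\langle\phi^2\rangle
#' \langle\sigma_r'^2\rangle}.  The state is marginally stable iff
#' \eqn{\rho < 1}, equivalently
#' \eqn{\langle\phi'^2\rangle(\langle\phi^2\rangle\langle\sigma_r'^2\rangle +
#' \langle\sigma_r^2\rangle) < \langle\sigma_z\rangle^{-1}}.
#'
#' @param moments a `"state_moments"` object evaluated on the MFT state.
#' @return the radius `rho`, with attribute `"marginal"` (`rho < 1`).
#' @export
marginal_stability_radius <- function(moments) {
  a <- moments$phip2 * moments$sz * moments$sr2
  b <- moments$phip2 * moments$sz * moments$phi2 * moments$srp2
  rad2 <- a / 2 + sqrt(4 * b + a^2) / 2
  stopifnot(rad2 >= 0)
  rho <- sqrt(rad2)
  attr(rho, "marginal") <- rho < 1
  rho
}

#' Limiting eigenvalue density of the switchlike update gate
#'
#' In the `alpha_z -> Inf` limit the density of the N Jacobian eigenvalues
#' associated with the `h` block converges to a point mass \eqn{1 - f_z} at 0
#' (frozen units), a point mass \eqn{f_z(1 - f_h)} at \eqn{-1} (active units
#' with saturated activation), and a uniform disk of density
#' \eqn{4/(\pi g_h^2)} carrying the remaining mass \eqn{f_z f_h}.  The disk
#' is centered at \eqn{-1} with radius \eqn{(g_h/2)\sqrt{f_z f_h}} (the
#' circular law of the active, unsaturated bulk; the factor 1/2 is the
#' closed output gate at `alpha_r = 0`), which makes the density normalize
#' exactly and reduce to the classical circular law when `f_z = f_h = 1`.
#'
#' @param f_z fraction of open update gates, in \[0, 1\].
#' @param f_h fraction of unsaturated activations, in \[0, 1\].
#' @param g_h activation gain.
#' @return list describing the three components; weights sum to 1.
#' @export
limiting_density_infinite_alpha_z <- function(f_z, f_h, g_h) {
  if (f_z < 0 || f_z > 1 || f_h < 0 || f_h > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  structure(list(weight_zero = 1 - f_z,
                 weight_minus_one = f_z * (1 - f_h),
                 disk_weight = f_z * f_h,
                 disk_center = -1,
                 disk_radius = g_h / 2 * sqrt(f_z * f_h),
                 disk_density = if (f_z * f_h > 0) 4 / (pi * g_h^2) else 0),
            class = "limiting_density")
}

#' Fraction of eigenvalues near the origin
#'
#' @param eigenvalues complex vector.
#' @param delta disk radius (default 0.05).
#' @return fraction with \eqn{|\lambda| < \delta}.
#' @export
near_zero_fraction <- function(eigenvalues, delta = 0.05) {
  mean(Mod(eigenvalues) < delta)
}

#' Fraction of empirical eigenvalues inside the predicted boundary
#'
#' A point is counted inside when the spectral-curve function is positive at
#' it (the interior of the support), with the boundary inflated by `tol`:
#' eigenvalues within distance `tol` of the zero-level set also count.
#'
#' @param eigenvalues complex vector.
#' @param curve a `"spectral_result"`.
#' @param tol boundary inflation, in spectral-curve function units resolved
#'   via a small outward probe.
#' @return fraction inside.
#' @export
fraction_inside_boundary <- function(eigenvalues, curve, tol = 0.02) {
  m <- curve$moments
  gv <- spectral_curve_value(m, eigenvalues, curve$tau_r)
  inside <- gv > 0
  # inflate: points slightly outside (G < 0) count if a probe of radius tol
  # in any axis direction lands inside
  out <- which(!inside)
  for (i in out) {
    lam <- eigenvalues[i]
    probes <- lam + tol * c(1, -1, 1i, -1i)
    if (any(spectral_curve_value(m, probes, curve$tau_r) > 0)) inside[i] <- TRUE
  }
  mean(inside)
}

#' Spectral pinching diagnostics over the update-gate gain
#'
#' For each `alpha_z` in `alpha_z_list`, relaxes the network into its steady
#' state, measures the moment set, and reports the spectral-curve leading
#' edge and imaginary-axis intercept together with the empirical fraction of
#' Jacobian eigenvalues within radius `delta` of the origin.  Optionally fits
#' the error-function form `c0 * erf(c1 * alpha_z)` to the near-zero fraction
#' and reports the fit.
#'
#' @param params a [network_params()] template (its `alpha_z` is replaced).
#' @param alpha_z_list update-gate gains to scan.
#' @param t_relax relaxation time before measuring.
#' @param delta near-zero disk radius.
#' @param dt integration step.
#' @return data frame with columns `alpha_z`, `leading_edge`,
#'   `imag_intercept`, `near_zero_fraction`; the erf fit (when it converges)
#'   is attached as attribute `"erf_fit"` with elements `c0`, `c1`,
#'   `r_squared`.
#' @export
pinching_diagnostic <- function(params, alpha_z_list, t_relax = 100,
                                delta = 0.05, dt = 0.05) {
  stopifnot(delta > 0)
  rows <- lapply(alpha_z_list, function(az) {
    p <- update_params(params, alpha_z = az)
    net <- make_network(p)
    traj <- simulate_network(net, t_final = t_relax, dt = dt, record_every = 4L)
    mom <- steady_state_moments(traj)
    sc <- spectral_curve(mom, tau_r = p$tau_r, n_grid = 300L)
    ev <- empirical_spectrum(instantaneous_jacobian(net, final_state(traj)))
    data.frame(alpha_z = az, leading_edge = sc$leading_edge,
               imag_intercept = sc$imag_intercept,
               near_zero_fraction = near_zero_fraction(ev, delta))
  })
  out <- do.call(rbind, rows)
  fit <- tryCatch({
    erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
    nl <- stats::nls(near_zero_fraction ~ c0 * erf(c1 * alpha_z), data = out,
                     start = list(c0 = max(out$near_zero_fraction), c1 = 0.1))
    pr <- stats::predict(nl)
    ssr <- sum((out$near_zero_fraction - pr)^2)
    sst <- sum((out$near_zero_fraction - mean(out$near_zero_fraction))^2)
    c(as.list(stats::coef(nl)), list(r_squared = 1 - ssr / max(sst, 1e-300)))
  }, error = function(e) NULL)
  attr(out, "erf_fit") <- fit
  out
}
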