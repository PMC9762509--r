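# Functional experiments: integration of inputs along the slow manifold of
# the marginally stable state, and gate-mediated reset of the memory trace.

#' Integrator experiment on the slow manifold
#'
#' With a switchlike update gate (large `alpha_z`) and gain inside the
#' marginal-stability window, the Jacobian acquires a cluster of near-zero
#' eigenvalues whose eigenvectors span an approximate continuous attractor.
#' The experiment (i) relaxes the network into its slow state, (ii) extracts
#' the Jacobian eigenvector with eigenvalue nearest zero, (iii) applies an
#' input pulse along its h components (and, for contrast, along the
#' eigenvector of a fast, strongly decaying mode), and (iv) tracks the excess
#' projection of the state onto the corresponding left eigenvector relative
#' to a no-input reference run.  Inputs along the slow manifold are
#' integrated and retained; inputs along fast modes decay on the O(1)
#' intrinsic timescale.
#'
#' @param params parameters with large `alpha_z` and `g_h` in the marginal
#'   window (e.g. `alpha_z = 30`, `g_h = 3`).
#' @param input_strengths input amplitudes to scan.
#' @param t_relax relaxation time before the pulse.
#' @param t_input pulse duration.
#' @param t_post post-pulse observation time (retention is measured 50 time
#'   units after input offset by default, so `t_post` must exceed
#'   `retention_delay`).
#' @param retention_delay delay after offset at which retention is measured.
#' @param eig_tol the slow eigenvalue must satisfy \eqn{|\lambda| <} this, or
#'   the parameters are rejected as outside the slow-mode regime.
#' @param dt integration step.
#' @return An object of class `"integrator_result"`: per-strength plateau and
#'   retention, the non-aligned retention, the slow eigenvalue, and the
#'   projection time series.
#' @export
integrator_experiment <- function(params, input_strengths = c(0.5, 1, 2),
                                  t_relax = 100, t_input = 10, t_post = 60,
                                  retention_delay = 50, eig_tol = 0.05,
                                  dt = 0.05) {
  stopifnot(t_post >= retention_delay)
  net <- make_network(params)
  relax <- simulate_network(net, t_final = t_relax, dt = dt, record_every = 10L)
  x0 <- final_state(relax)
  n <- params$n_units

  J <- instantaneous_jacobian(net, x0)
  er <- eigen(J)
  el <- eigen(t(J))
  if (min(Mod(er$values)) >= eig_tol)
    stop(sprintf("no Jacobian eigenvalue with |lambda| < %g (closest: %g); not in the slow-mode regime",
                 eig_tol, min(Mod(er$values))), call. = FALSE)
  # left eigenvectors of a clustered nonnormal spectrum come out of LAPACK
  # with limited accuracy; a couple of inverse-iteration steps restores the
  # biorthogonality that the projection diagnostics rely on
  refine_left <- function(u, lambda) {
    A <- t(J) - (lambda + 1e-9) * diag(nrow(J))
    for (i in 1:2) { u <- solve(A, u); u <- u / sqrt(sum(Mod(u)^2)) }
    u
  }
  # among the near-zero cluster, drive a collective, non-defective mode:
  # many frozen units participating (high participation ratio of the h part)
  # and a usable left-right pairing, so projections are well conditioned
  cl <- which(Mod(er$values) < eig_tol / 50)
  if (!length(cl)) cl <- which(Mod(er$values) < eig_tol)
  pr_h <- vapply(cl, function(i) {
    vh2 <- Mod(er$vectors[1:n, i])^2
    sum(vh2)^2 / sum(vh2^2)
  }, numeric(1))
  cosuv <- vapply(cl, function(i) {
    j <- which.min(Mod(el$values - er$values[i]))
    abs(sum(el$vectors[, j] * er$vectors[, i]))
  }, numeric(1))
  ok <- cosuv > 0.05
  if (!any(ok)) ok <- cosuv >= max(cosuv)
  i_slow <- cl[ok][which.max(pr_h[ok])]
  lambda_slow <- er$values[i_slow]
  v <- er$vectors[, i_slow]
  j_left <- which.min(Mod(el$values - lambda_slow))
  u <- Conj(refine_left(el$vectors[, j_left], el$values[j_left]))
  u <- u / sum(Conj(u) * v)              # biorthonormal scaling u^H v = 1

  v_h <- Re(v[1:n])
  dir_aligned <- v_h / sqrt(sum(v_h^2))
  # contrast direction: a well-separated fast mode from the stable disk,
  # with substantial h content (the pure z/r relaxation modes at -1/tau have
  # none and cannot be driven through h).  Its response is tracked through
  # its own left eigenvector, for which the linear decay e^{Re(lambda) t} is
  # exact; the probe amplitude is kept small so the linearization holds.
  slow_set <- which(Mod(el$values) < 2 * eig_tol)
  h_content <- sqrt(colSums(Mod(er$vectors[1:n, , drop = FALSE])^2))
  cand <- which(h_content > 0.15 & Re(er$values) < -0.3 & Re(er$values) > -0.95)
  if (!length(cand))
    stop("no driveable fast mode found for the contrast input", call. = FALSE)
  i_fast <- cand[which.max(h_content[cand])]
  v_fast <- er$vectors[, i_fast]
  j_fast <- which.min(Mod(el$values - er$values[i_fast]))
  u_fast <- Conj(refine_left(el$vectors[, j_fast], el$values[j_fast]))
  u_fast <- u_fast / sum(Conj(u_fast) * v_fast)
  vf_h <- Re(v_fast[1:n])
  dir_fast <- vf_h / sqrt(sum(vf_h^2))

  t_total <- t_input + t_post
  run_from_x0 <- function(inputs) {
    simulate_network(net, t_final = t_total, dt = dt, record_every = 4L,
                     init = x0, inputs = inputs)
  }
  ref <- run_from_x0(list())
  proj_series <- function(traj, uvec = u) {
    dx <- cbind(traj$h - ref$h, traj$z - ref$z, traj$r - ref$r)
    abs(dx %*% Conj(uvec))[, 1]
  }
  idx_at <- function(traj, t) which.min(abs(traj$times - t))

  runs <- lapply(input_strengths, function(s) {
    tr <- run_from_x0(list(input_protocol("h", s * dir_aligned, 0, t_input,
                                          generator = "eigenvector_aligned")))
    pr <- proj_series(tr)
    i_off <- idx_at(tr, t_input); i_ret <- idx_at(tr, t_input + retention_delay)
    list(strength = s, projection = pr, times = tr$times,
         plateau = pr[i_off],
         retention = if (pr[i_off] > 0) pr[i_ret] / pr[i_off] else 0)
  })
  s_na <- min(c(input_strengths, 0.5))
  tr_na <- run_from_x0(list(input_protocol("h", s_na * dir_fast, 0, t_input)))
  pr_na <- proj_series(tr_na, u_fast)
  i_off <- idx_at(tr_na, t_input); i_ret <- idx_at(tr_na, t_input + retention_delay)
  retention_na <- if (pr_na[i_off] > 0) pr_na[i_ret] / pr_na[i_off] else 0

  structure(list(
    strengths = input_strengths,
    plateau = vapply(runs, `[[`, numeric(1), "plateau"),
    retention = vapply(runs, `[[`, numeric(1), "retention"),
    retention_nonaligned = retention_na,
    lambda_slow = lambda_slow, lambda_fast = er$values[i_fast],
    n_slow_modes = length(slow_set),
    runs = runs, params = params), class = "integrator_result")
}

#' @export
print.integrator_result <- function(x, ...) {
  cat(sprintf("Integrator experiment (slow eigenvalue %.4g + %.4gi):\n",
              Re(x$lambda_slow), Im(x$lambda_slow)))
  for (i in seq_along(x$strengths))
    cat(sprintf("  strength %g: plateau %.4g, retention %.3f\n",
                x$strengths[i], x$plateau[i], x$retention[i]))
  cat(sprintf("  non-aligned retention: %.3f\n", x$retention_nonaligned))
  invisible(x)
}

#' Reset experiment: erasing the memory trace
#'
#' Two reset mechanisms for a network holding a memory state:
#' `"gate_clamp"` pins the output gate to zero for a window, so the recurrent
#' drive vanishes and `h` decays at rate \eqn{\sigma_z}; `"z_pulse"` applies
#' a positive static input to the update gate, which shifts
#' \eqn{\langle\sigma_z\rangle} above the marginal-stability threshold and
#' induces chaos that scrambles the state.  The reported statistic is the
#' normalized projection of `h(t)` onto the pre-reset state; a projection
#' below 0.1 after the reset window counts as a successful erase.
#'
#' @param params network parameters (for `"z_pulse"`, the marginal state:
#'   large `alpha_z`, `g_h` in the window).
#' @param mode `"gate_clamp"` or `"z_pulse"`.
#' @param pulse_strength mean of the `I^z` pulse (mode `"z_pulse"`).
#' @param t_memory time to settle into the memory state before the reset.
#' @param t_reset duration of the reset window.
#' @param t_post observation time after the window.
#' @param dt integration step.
#' @param infinite_gate handling of `alpha = Inf` gates; the reset threshold
#'   is sharpest in the true binary-gate limit, so the Heaviside gate is the
#'   default here (the frozen units are then exactly frozen between pulses).
#' @return An object of class `"reset_result"`: `times`, `projection` (onto
#'   the pre-reset state), `h_norm`, `success`, and the window bounds.
#' @export
reset_experiment <- function(params, mode = c("z_pulse", "gate_clamp"),
                             pulse_strength = 1, t_memory = 50, t_reset = 20,
                             t_post = 50, dt = 0.05,
                             infinite_gate = c("heaviside", "surrogate")) {
  mode <- match.arg(mode)
  infinite_gate <- match.arg(infinite_gate)
  net <- make_network(params)
  n <- params$n_units

  if (mode == "z_pulse") {
    ip <- input_protocol("z", rep(pulse_strength, n),
                         t_on = t_memory, t_off = t_memory + t_reset,
                         generator = "reset_pulse")
    traj <- simulate_network(net, t_final = t_memory + t_reset + t_post,
                             dt = dt, record_every = 4L, inputs = list(ip),
                             infinite_gate = infinite_gate)
  } else {
    seg1 <- simulate_network(net, t_final = t_memory, dt = dt, record_every = 4L)
    net_clamped <- make_network(params,
                                gate_override = modifyList(
                                  as.list(net$gate_override), list(r = 0)))
    seg2 <- simulate_network(net_clamped, t_final = t_reset, dt = dt,
                             record_every = 4L, init = final_state(seg1))
    seg3 <- simulate_network(net, t_final = t_post, dt = dt, record_every = 4L,
                             init = final_state(seg2))
    traj <- stitch_trajectories(seg1, seg2, seg3)
  }

  i_ref <- which.min(abs(traj$times - t_memory))
  h_ref <- traj$h[i_ref, ]
  nr <- sqrt(rowSums(traj$h^2))
  proj <- abs(traj$h %*% h_ref)[, 1] / (nr * sqrt(sum(h_ref^2)))
  proj[nr < 1e-12] <- 0
  i_end <- length(traj$times)
  structure(list(times = traj$times, projection = proj, h_norm = nr,
                 reset_window = c(t_memory, t_memory + t_reset),
                 final_projection = proj[i_end],
                 success = proj[i_end] < 0.1,
                 mode = mode, params = params), class = "reset_result")
}

#' @export
print.reset_result <- function(x, ...) {
  cat(sprintf("Reset experiment (%s): final projection on pre-reset state = %.3f (%s)\n",
              x$mode, x$final_projection,
              if (x$success) "erased" else "retained"))
  invisible(x)
}

# concatenate trajectories from chained runs (shared endpoint dropped)
stitch_trajectories <- function(...) {
  segs <- list(...)
  out <- segs[[1]]
  for (s in segs[-1]) {
    off <- max(out$times)
    out$times <- c(out$times, off + s$times[-1])
    out$h <- rbind(out$h, s$h[-1, , drop = FALSE])
    out$z <- rbind(out$z, s$z[-1, , drop = FALSE])
    out$r <- rbind(out$r, s$r[-1, , drop = FALSE])
  }
  out
}
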