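# Phase-diagram machinery: region classification, the discontinuous dynamical
# transition, transient-time scaling, input-induced chaos, and the critical
# line under quenched static input.
#
# Regions (bias-free plane (g_h, alpha_r)):
#   1  zero FP is the only solution, globally stable
#   2  zero FP stable, unstable fixed points proliferate (nontrivial MFT
#      solutions exist) without dynamical signature
#   3  zero FP stable but coexists with a chaotic set (lambda_max > 0 from
#      large-norm initial conditions)
#   4  zero FP unstable: chaotic attractor
#   5  overlay: the chaotic side can be made marginally stable at
#      alpha_z = Inf (disk radius rho < 1)

#' Ensemble vote on the sign of the maximal Lyapunov exponent
#'
#' Runs `n_trials` simulations from independent random initial conditions of
#' scale `init_scale` and calls the point chaotic when at least
#' `positive_votes` of them have \eqn{\lambda_{max}} above `threshold`.
#'
#' @param net a [make_network()] network.
#' @param n_trials number of trials (default 8).
#' @param positive_votes votes required to call "positive" (default 6).
#' @param threshold exponent threshold (default +0.02).
#' @param init_scale standard deviation of the initial state.
#' @param t_total,t_transient per-trial integration budget.
#' @param inputs optional input protocols applied in every trial.
#' @param trial_seed base seed for the trial substreams.
#' @return list with `positive` (logical), `lambda` (per-trial exponents),
#'   `votes`, and `collapsed` (per-trial: did the trajectory end on the zero
#'   fixed point?).  The collapse flag separates the two branches of
#'   \eqn{\lambda_{max}} at finite N, where chaotic transients blur the
#'   discontinuous transition.
#' @export
lambda_max_vote <- function(net, n_trials = 8L, positive_votes = 6L,
                            threshold = 0.02, init_scale = 1,
                            t_total = 200, t_transient = 50,
                            inputs = list(), trial_seed = NULL) {
  seed <- if (is.null(trial_seed)) net$params$seed else trial_seed
  trials <- lapply(seq_len(n_trials), function(i) {
    res <- lyapunov_spectrum(net, k = 1L, t_total = t_total,
                             t_transient = t_transient,
                             init_scale = init_scale, inputs = inputs,
                             init_seed = substream_seed(seed, "trials") + i)
    list(lambda = res$exponents[1],
         collapsed = mean(res$final$h^2) < 1e-8)
  })
  lam <- vapply(trials, `[[`, numeric(1), "lambda")
  collapsed <- vapply(trials, `[[`, logical(1), "collapsed")
  votes <- sum(lam > threshold)
  list(positive = votes >= positive_votes, lambda = lam, votes = votes,
       collapsed = collapsed)
}

#' Classify a point of the bias-free phase diagram
#'
#' Combines (i) the fixed-point instability criterion on the zero fixed
#' point, (ii) existence of nontrivial mean-field solutions, (iii) an
#' ensemble estimate of \eqn{\lambda_{max}} from initial conditions far from
#' the origin (the chaotic set coexisting with the stable zero fixed point
#' is invisible from small initial conditions), and (iv) the binary-gate
#' disk radius for the marginal-stability overlay.
#'
#' @param params a [network_params()] object with all biases zero.
#' @param n_trials,t_sim simulation budget for the chaotic-set vote.
#' @param threshold,positive_votes vote rule passed to [lambda_max_vote()].
#' @return An object of class `"phase_point"`: `region` in 1..4,
#'   `marginal_overlay` (region-5 flag), and the `evidence` list.
#' @export
classify_point <- function(params, n_trials = 8L, t_sim = 200,
                           threshold = 0.02, positive_votes = 6L) {
  stopifnot(inherits(params, "network_params"))
  if (params$beta_h != 0 || params$beta_z != 0 || params$beta_r != 0)
    stop("region semantics are defined for the bias-free network", call. = FALSE)
  p_finite <- if (is.infinite(params$alpha_z))
    update_params(params, alpha_z = 100) else params

  m0 <- zero_fp_moments(params)
  zero_unstable <- fp_unstable(m0)
  mft <- solve_fixed_point(params)
  nonzero_exists <- mft$branch == "nonzero"

  init_scale <- if (nonzero_exists) sqrt(max(mft$delta_h, 0.25)) else 1
  vote <- lambda_max_vote(make_network(p_finite), n_trials = n_trials,
                          positive_votes = positive_votes,
                          threshold = threshold, init_scale = init_scale,
                          t_total = t_sim, t_transient = t_sim / 2)

  region <- if (zero_unstable) 4L
    else if (vote$positive) 3L
    else if (nonzero_exists) 2L
    else 1L
  if (region == 3L && !nonzero_exists)
    stop("inconsistent evidence: lambda_max > 0 voted but no nontrivial MFT solution",
         call. = FALSE)

  mom_binary <- fixed_point_moments(update_params(params, alpha_z = Inf),
                                    if (nonzero_exists) mft else
                                      solve_fixed_point(params, "zero"))
  rho <- marginal_stability_radius(mom_binary)
  overlay <- region %in% c(3L, 4L) && rho < 1

  structure(list(params = params, region = region,
                 marginal_overlay = overlay,
                 evidence = list(zero_fp_unstable = zero_unstable,
                                 nonzero_mft = mft,
                                 lambda = vote$lambda, votes = vote$votes,
                                 rho = as.numeric(rho))),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("Phase point (g_h = %g, alpha_r = %g, alpha_z = %s): region %d%s\n",
              x$params$g_h, x$params$alpha_r,
              if (is.infinite(x$params$alpha_z)) "Inf" else x$params$alpha_z,
              x$region, if (x$marginal_overlay) " (+5 marginal overlay)" else ""))
  invisible(x)
}

#' Critical output-gate gain of the discontinuous dynamical transition
#'
#' Smallest `alpha_r` at which an ensemble of trajectories initialized at
#' large norm sustains \eqn{\lambda_{max} > 0} over the observation window,
#' located by bisection with the stochastic vote rule.  This is the
#' dynamical transition: it lies strictly above the fixed-point
#' proliferation threshold [alpha_r_fp_star()], and \eqn{\lambda_{max}}
#' jumps discontinuously across it.  Valid for `g_h < 2` (where the zero
#' fixed point is still stable) and small `alpha_z`.
#'
#' @param g_h activation gain in (sqrt(8/3), 2).
#' @param n_units working network size.
#' @param window `alpha_r` search window.
#' @param resolution bisection resolution.
#' @param n_trials,t_sim,threshold,positive_votes vote rule.
#' @param seed seed for couplings and trials.
#' @return critical `alpha_r` (NA with diagnostic when no transition in the
#'   window), with attribute `"bracket"`: the final bisection bracket and the
#'   mean \eqn{\lambda_{max}} on either side (for jump-size checks).
#' @export
alpha_r_dmft_star <- function(g_h, n_units = 400L, window = c(0, 12),
                              resolution = 0.25, n_trials = 8L, t_sim = 200,
                              threshold = 0.02, positive_votes = 6L,
                              seed = 1L) {
  if (g_h >= 2)
    stop("the discontinuous transition is defined for g_h < 2 (stable zero FP)",
         call. = FALSE)
  probe <- function(ar) {
    p <- network_params(n_units, g_h = g_h, alpha_r = ar, seed = seed)
    mft <- solve_fixed_point(p)
    scale <- if (mft$branch == "nonzero") sqrt(max(mft$delta_h, 0.25)) else 1
    lambda_max_vote(make_network(p), n_trials = n_trials,
                    positive_votes = positive_votes, threshold = threshold,
                    init_scale = scale, t_total = t_sim,
                    t_transient = t_sim / 2, trial_seed = seed)
  }
  lo <- window[1]; hi <- window[2]
  v_lo <- probe(lo); v_hi <- probe(hi)
  if (v_lo$positive) return(structure(lo, bracket = NULL))
  if (!v_hi$positive) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf(
      "no sustained chaos for alpha_r in [%g, %g] at g_h = %g", lo, hi, g_h)
    return(out)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    v <- probe(mid)
    if (v$positive) { hi <- mid; v_hi <- v } else { lo <- mid; v_lo <- v }
  }
  out <- (lo + hi) / 2
  # branch-conditioned means: trials that collapse onto the stable FP sample
  # the stable branch of lambda_max, sustained trials the chaotic-set branch
  lam_stable <- v_lo$lambda[v_lo$collapsed]
  if (!length(lam_stable)) lam_stable <- v_lo$lambda
  lam_chaos <- v_hi$lambda[!v_hi$collapsed & v_hi$lambda > threshold]
  if (!length(lam_chaos)) lam_chaos <- v_hi$lambda
  attr(out, "bracket") <- list(lo = lo, hi = hi,
                               lambda_lo = mean(v_lo$lambda),
                               lambda_hi = mean(v_hi$lambda),
                               lambda_stable_branch = mean(lam_stable),
                               lambda_chaotic_branch = mean(lam_chaos))
  out
}

#' Transient time versus system size
#'
#' In the coexistence regime (region 3) chaotic transients eventually
#' collapse onto the stable zero fixed point, with a collapse time that
#' grows with N.  For each N, runs `trials` simulations from large-norm
#' initial conditions and records the first time the population variance of
#' `h` drops below `collapse_tol` (censored at `t_max`).
#'
#' @param params parameter template (its `n_units` is replaced).
#' @param n_list network sizes.
#' @param trials trials per size.
#' @param t_max per-trial time budget.
#' @param collapse_tol variance threshold defining collapse.
#' @param init_scale initial-state scale.
#' @return data frame with one row per size: `n_units`, `median_transient`,
#'   `n_collapsed`, plus all transient times as attribute `"times"`.
#' @export
transient_time_scaling <- function(params, n_list, trials = 6L, t_max = 400,
                                   collapse_tol = 1e-8, init_scale = 1) {
  res <- lapply(n_list, function(nn) {
    p <- update_params(params, n_units = nn)
    net <- make_network(p)
    tt <- vapply(seq_len(trials), function(i) {
      traj <- simulate_network(net, t_final = t_max, record_every = 4L,
                               init_scale = init_scale,
                               init_seed = substream_seed(p$seed, "trials") + i)
      pv <- population_variance(traj)
      hit <- which(pv < collapse_tol)
      if (length(hit)) traj$times[hit[1]] else t_max
    }, numeric(1))
    data.frame(n_units = nn, median_transient = median(tt),
               n_collapsed = sum(tt < t_max))
  })
  out <- do.call(rbind, res)
  attr(out, "times") <- res
  out
}

#' Scan for input-induced or input-suppressed chaos
#'
#' For each grid point, estimates \eqn{\lambda_{max}} with and without a
#' quenched Gaussian static drive of standard deviation `sigma_h`, frozen
#' per trial, with no input to the gates, and reports a verdict:
#' `"induced"` when the vote flips negative to positive, `"suppressed"` when
#' the mean exponent drops by more than 0.02, `"neutral"` otherwise.
#'
#' @param grid data frame with columns `g_h` and `alpha_r`.
#' @param params parameter template.
#' @param sigma_h input standard deviation (0 gives a neutral scan).
#' @param input_mode `"activation_bias"` (default): the quenched drive is a
#'   frozen per-unit bias inside the activation argument, the drive under
#'   which the induced transition occurs; `"additive_h"`: additive static
#'   input to the `h` equation, which predominantly stabilizes.
#' @param n_trials,t_sim,threshold,positive_votes vote rule.
#' @return data frame: grid columns plus `lambda_no_input`,
#'   `lambda_with_input`, `votes_no_input`, `votes_with_input`, `verdict`.
#' @export
input_induced_chaos_scan <- function(grid, params, sigma_h = 0.5,
                                     input_mode = c("activation_bias",
                                                    "additive_h"),
                                     n_trials = 8L, t_sim = 200,
                                     threshold = 0.02, positive_votes = 6L) {
  input_mode <- match.arg(input_mode)
  tgt <- if (input_mode == "activation_bias") "phi" else "h"
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- update_params(params, g_h = grid$g_h[i], alpha_r = grid$alpha_r[i])
    net <- make_network(p)
    mft <- solve_fixed_point(p)
    scale <- if (mft$branch == "nonzero") sqrt(max(mft$delta_h, 0.25)) else 1
    v0 <- lambda_max_vote(net, n_trials, positive_votes, threshold,
                          init_scale = scale, t_total = t_sim,
                          t_transient = t_sim / 2)
    v1 <- vapply(seq_len(n_trials), function(j) {
      ip <- gaussian_input(tgt, p$n_units, sigma_h,
                           seed = substream_seed(p$seed, "input") + j)
      estimate_lambda_max(net, t_total = t_sim, t_transient = t_sim / 2,
                          init_scale = scale, inputs = list(ip),
                          init_seed = substream_seed(p$seed, "trials") + j)
    }, numeric(1))
    votes1 <- sum(v1 > threshold)
    verdict <- if (sigma_h == 0) "neutral"
      else if (!v0$positive && votes1 >= positive_votes) "induced"
      else if (mean(v1) < mean(v0$lambda) - 0.02) "suppressed"
      else "neutral"
    data.frame(g_h = grid$g_h[i], alpha_r = grid$alpha_r[i],
               lambda_no_input = mean(v0$lambda), lambda_with_input = mean(v1),
               votes_no_input = v0$votes, votes_with_input = votes1,
               verdict = verdict)
  })
  do.call(rbind, rows)
}

#' Critical line under quenched static input
#'
#' Locus in the (g_h, alpha_r) plane where the fixed-point instability
#' criterion holds with equality under the input-augmented mean-field
#' closure (see [solve_fixed_point()] for the two drive modes).  Along the
#' g_h axis the drive suppresses chaos (the critical gain moves above 2); at
#' large `alpha_r` the line dips below `g_h = 2`, creating the band where a
#' static drive induces chaos.
#'
#' @param sigma_h input standard deviation.
#' @param input_mode drive mode, as in [solve_fixed_point()].
#' @param g_h_grid gains to scan.
#' @param params parameter template (biases zero, finite alpha_z).
#' @param window `alpha_r` bisection window.
#' @param resolution bisection resolution.
#' @return data frame `g_h`, `alpha_r_crit` (NA where the MFT does not
#'   converge or no crossing exists in the window; flagged in `note`).
#' @export
biased_critical_line <- function(sigma_h, g_h_grid,
                                 params = network_params(2, g_h = 1),
                                 input_mode = c("activation_bias",
                                                "additive_h"),
                                 window = c(0, 40), resolution = 1e-3) {
  input_mode <- match.arg(input_mode)
  unstable_at <- function(g, ar) {
    p <- update_params(params, g_h = g, alpha_r = ar)
    sol <- solve_fixed_point(p, input_variance_h = sigma_h^2,
                             input_mode = input_mode)
    # near the fold the damped iteration slows critically; a small residual
    # is as good as formal convergence for the stability classification
    if (!sol$converged && sol$residual > 1e-6) return(NA)
    fp_unstable(fixed_point_moments(p, sol))
  }
  rows <- lapply(g_h_grid, function(g) {
    u0 <- unstable_at(g, window[1])
    if (is.na(u0))
      return(data.frame(g_h = g, alpha_r_crit = NA_real_, note = "mft_nonconverged"))
    if (isTRUE(u0))
      return(data.frame(g_h = g, alpha_r_crit = window[1], note = "unstable_at_0"))
    u1 <- unstable_at(g, window[2])
    if (!isTRUE(u1))
      return(data.frame(g_h = g, alpha_r_crit = NA_real_, note = "no_crossing"))
    lo <- window[1]; hi <- window[2]
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      um <- unstable_at(g, mid)
      if (is.na(um)) return(data.frame(g_h = g, alpha_r_crit = NA_real_,
                                       note = "mft_nonconverged"))
      if (um) hi <- mid else lo <- mid
    }
    data.frame(g_h = g, alpha_r_crit = (lo + hi) / 2, note = "ok")
  })
  do.call(rbind, rows)
}
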