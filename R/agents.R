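# The learning agent: a Kalman filter tracking both options' values, with
# Weber-scaled learning noise on the update of the chosen option, decay of
# the unchosen option's value toward the 0.5 baseline, and a softmax choice
# policy. All values are on the 0-1 scale (points / 100).

#' Construct agent parameters
#'
#' Bundles the four free parameters of the noisy Kalman-filter learning agent
#' together with its fixed scaling constants. The drift variance `v_d` is
#' parameterized through the asymptotic Kalman gain `alpha`: the steady-state
#' gain the filter would reach for an option chosen on every trial.
#'
#' @param alpha Asymptotic Kalman gain, in (0, 1).
#' @param zeta Learning-noise Weber fraction (>= 0): the SD of the random
#'   corruption of each value update is `zeta * |k * prediction error|`.
#' @param delta Decay rate of the unchosen option's value toward 0.5, in
#'   \[0, 1\].
#' @param tau Softmax choice temperature (>= 0); `tau = 0` is the greedy
#'   argmax policy with a fair-coin tie-break.
#' @param v_s Sampling variance of rescaled rewards (fixed constant 0.0163).
#' @param v0 Initial posterior variance (fixed constant 0.0214).
#' @param v_d Drift variance; by default derived from `alpha` via
#'   [drift_from_gain()]. Supply directly (with `alpha = NA`) for agents
#'   parameterized by generative variances, e.g. the optimal agent.
#' @return An object of class `nb_params`.
#' @export
agent_params <- function(alpha, zeta = 0, delta = 0, tau = 0,
                         v_s = NB_VS, v0 = NB_V0, v_d = NULL) {
  if (is.null(v_d)) {
    v_d <- drift_from_gain(alpha, v_s)
  }
  stopifnot(zeta >= 0, delta >= 0, delta <= 1, tau >= 0, v_s > 0, v0 > 0,
            v_d >= 0)
  structure(list(alpha = alpha, zeta = zeta, delta = delta, tau = tau,
                 v_s = v_s, v0 = v0, v_d = v_d),
            class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat("<nb_params>",
      sprintf("alpha=%.4g zeta=%.4g delta=%.4g tau=%.4g", x$alpha, x$zeta,
              x$delta, x$tau),
      sprintf("v_s=%.4g v0=%.4g v_d=%.4g", x$v_s, x$v0, x$v_d), "\n")
  invisible(x)
}

#' Drift variance implied by an asymptotic Kalman gain
#'
#' Under repeated observation of one option, the variance recursion
#' `v <- (1 - k) v + v_d` with `k = v / (v + v_s)` converges to a fixed point
#' whose gain is `alpha` when `v_d = alpha^2 v_s / (1 - alpha)`.
#'
#' @param alpha Asymptotic gain in (0, 1).
#' @param v_s Sampling variance.
#' @return Drift variance `v_d`.
#' @export
drift_from_gain <- function(alpha, v_s = NB_VS) {
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must lie strictly in (0, 1)")
  }
  alpha^2 * v_s / (1 - alpha)
}

#' Asymptotic Kalman gain implied by a drift variance
#'
#' Inverse of [drift_from_gain()]: solves `v_s a^2 + v_d a - v_d = 0` for the
#' positive root.
#'
#' @param v_d Drift variance (>= 0).
#' @param v_s Sampling variance.
#' @return Asymptotic gain in \[0, 1).
#' @export
gain_from_drift <- function(v_d, v_s = NB_VS) {
  stopifnot(v_d >= 0, v_s > 0)
  (-v_d + sqrt(v_d^2 + 4 * v_s * v_d)) / (2 * v_s)
}

#' Kalman gain
#'
#' `k = v_prev / (v_prev + v_s)`, the trial-wise weight on the prediction
#' error given the current posterior variance.
#'
#' @param v_prev Posterior variance before the update (>= 0).
#' @param v_s Sampling variance (> 0).
#' @return Gain in \[0, 1).
#' @export
kalman_gain <- function(v_prev, v_s = NB_VS) {
  stopifnot(all(v_prev >= 0), v_s > 0)
  v_prev / (v_prev + v_s)
}

#' Initial agent state
#'
#' Both value means start at the 0.5 baseline and both posterior variances at
#' `v0`.
#'
#' @param params An `nb_params` object.
#' @return A list with components `x` (length-2 means) and `v` (variances).
#' @export
init_state <- function(params) {
  list(x = c(0.5, 0.5), v = c(params$v0, params$v0))
}

#' Update the chosen option after an observed reward
#'
#' Kalman update of the chosen option's value mean, corrupted by additive
#' Gaussian learning noise whose SD follows Weber scaling:
#' `eta = zeta * |k * (r - x)|`. The posterior mean is not clipped; the
#' variance update `v <- (1 - k) v + v_d` is deterministic.
#'
#' @param state Agent state as returned by [init_state()].
#' @param choice Chosen option (1 or 2).
#' @param reward Observed reward on the 0-1 scale.
#' @param params An `nb_params` object.
#' @return A list with the new `state` and an update `trace` (gain `k`,
#'   prediction error `pe`, noise SD `eta`, realized noise `eps`).
#' @export
update_chosen <- function(state, choice, reward, params) {
  stopifnot(choice %in% c(1, 2), reward >= 0, reward <= 1)
  k <- kalman_gain(state$v[choice], params$v_s)
  pe <- reward - state$x[choice]
  eta <- params$zeta * abs(k * pe)
  eps <- if (eta > 0) rnorm(1, 0, eta) else 0
  state$x[choice] <- state$x[choice] + k * pe + eps
  state$v[choice] <- (1 - k) * state$v[choice] + params$v_d
  list(state = state, trace = list(k = k, pe = pe, eta = eta, eps = eps))
}

#' Update the unchosen option
#'
#' The unchosen option's value decays toward the 0.5 baseline at rate `delta`
#' and its posterior variance grows by the drift variance (gain 0, no
#' observation).
#'
#' @inheritParams update_chosen
#' @return The new state.
#' @export
update_unchosen <- function(state, choice, params) {
  stopifnot(choice %in% c(1, 2))
  u <- if (choice == 1) 2 else 1
  state$x[u] <- state$x[u] + params$delta * (0.5 - state$x[u])
  state$v[u] <- state$v[u] + params$v_d
  state
}

#' Softmax probability of choosing option 1
#'
#' `p = 1 / (1 + exp(-(x1 - x2) / tau))`; at `tau = 0` the policy is a greedy
#' argmax with probability 0.5 on exact ties.
#'
#' @param state Agent state.
#' @param tau Choice temperature (>= 0).
#' @return Probability of choosing option 1.
#' @export
choice_prob <- function(state, tau) {
  stopifnot(tau >= 0)
  d <- state$x[1] - state$x[2]
  if (tau == 0) {
    return(if (d > 0) 1 else if (d < 0) 0 else 0.5)
  }
  plogis(d / tau)
}

#' Optimal learning agent for a task condition
#'
#' A Kalman filter whose variances are set to the condition's effective
#' generative values, choosing greedily with no learning noise and no decay.
#'
#' @param spec An `nb_genspec` object from [compute_effective_variances()].
#' @return An `nb_params` object with `zeta = delta = tau = 0`.
#' @export
make_optimal_agent <- function(spec) {
  stopifnot(inherits(spec, "nb_genspec"))
  agent_params(alpha = NA_real_, zeta = 0, delta = 0, tau = 0,
               v_s = spec$v_s_eff, v0 = NB_V0, v_d = spec$v_d_eff)
}

#' Serialize agent parameters to JSON
#'
#' Writes all four free parameters plus the fixed constants so a parameter
#' set is self-describing.
#'
#' @param params An `nb_params` object.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly if written to file.
#' @export
params_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read agent parameters from JSON
#'
#' @param path File path or JSON string produced by [params_to_json()].
#' @return An `nb_params` object.
#' @export
params_from_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  agent_params(alpha = if (is.null(p$alpha)) NA_real_ else p$alpha,
               zeta = p$zeta, delta = p$delta, tau = p$tau,
               v_s = p$v_s, v0 = p$v0, v_d = p$v_d)
}
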