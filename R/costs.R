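# Marginal and joint reward costs of learning noise and choice temperature.
# Costs are defined relative to an otherwise-identical agent with the varied
# source of variability removed: C_x = 100 * (1 - excess(x) / excess(0)),
# where "excess" is the mean obtained-minus-foregone reward.

#' Mean reward excess of an agent on a schedule
#'
#' Mean over trials and simulations of the obtained minus the foregone
#' reward (both options' realized rewards are pre-generated in the blocks;
#' the agent only observes the chosen one).
#'
#' @param params An `nb_params` object.
#' @param blocks Block data.frame for one condition.
#' @param n_sims Number of simulated traversals of the schedule.
#' @return Mean reward excess in points per trial.
#' @export
reward_excess <- function(params, blocks, n_sims = 1000) {
  stopifnot(inherits(params, "nb_params"))
  cpp_reward_excess(blocks$reward_1, blocks$reward_2, reinit_flags(blocks),
                    params$zeta, params$delta, params$tau,
                    params$v_s, params$v_d, params$v0, as.integer(n_sims))
}

# Copy of params with one or two variability parameters replaced.
with_variability <- function(params, zeta = NULL, tau = NULL) {
  p <- params
  if (!is.null(zeta)) p$zeta <- zeta
  if (!is.null(tau)) p$tau <- tau
  p
}

#' Marginal reward-cost curve of one source of variability
#'
#' Varies learning noise (`zeta`) or choice temperature (`tau`) over a grid
#' starting at 0 while holding all other parameters constant, and computes
#' the fractional loss of reward excess relative to the grid's zero point:
#' `C(g) = 100 * (1 - excess(g) / excess(0))`, in percent.
#'
#' @param base_params Base `nb_params` (all other parameters held constant).
#' @param varied `"zeta"` or `"tau"`.
#' @param grid Parameter grid; must start at 0.
#' @param blocks Block data.frame for one condition.
#' @param n_sims Simulated traversals per grid point.
#' @return An `nb_costcurve` data.frame with columns `value` and `cost`,
#'   and attributes `varied`, `condition`, `baseline_excess`, `n_sims`.
#' @export
marginal_cost_curve <- function(base_params, varied = c("zeta", "tau"), grid,
                                blocks, n_sims = 1000) {
  varied <- match.arg(varied)
  if (grid[1] != 0) stop("marginal_cost_curve: grid must start at 0")
  excess <- vapply(grid, function(g) {
    p <- if (varied == "zeta") with_variability(base_params, zeta = g)
         else with_variability(base_params, tau = g)
    reward_excess(p, blocks, n_sims)
  }, numeric(1))
  if (excess[1] <= 0) {
    stop("marginal_cost_curve: baseline reward excess is not positive; ",
         "the cost ratio is uninformative")
  }
  out <- data.frame(value = grid, cost = 100 * (1 - excess / excess[1]))
  attr(out, "varied") <- varied
  attr(out, "condition") <- unique(blocks$condition)
  attr(out, "baseline_excess") <- excess[1]
  attr(out, "n_sims") <- n_sims
  class(out) <- c("nb_costcurve", "data.frame")
  out
}

#' Joint reward cost of learning noise and choice temperature
#'
#' Fractional loss of reward excess of an agent with both sources of
#' variability, relative to the same agent with `zeta = tau = 0`.
#'
#' @param base_params Base `nb_params`.
#' @param zeta,tau Variability parameters of the evaluated agent.
#' @param blocks Block data.frame for one condition.
#' @param n_sims Simulated traversals per evaluation.
#' @return Joint cost in percent.
#' @export
joint_cost <- function(base_params, zeta, tau, blocks, n_sims = 1000) {
  e0 <- reward_excess(with_variability(base_params, zeta = 0, tau = 0),
                      blocks, n_sims)
  if (e0 <= 0) stop("joint_cost: baseline reward excess is not positive")
  e <- reward_excess(with_variability(base_params, zeta = zeta, tau = tau),
                     blocks, n_sims)
  100 * (1 - e / e0)
}

#' Invert a cost curve at a target cost
#'
#' Finds the parameter value achieving a target marginal cost by monotone
#' (isotonic-smoothed) linear interpolation of the curve.
#'
#' @param curve An `nb_costcurve` from [marginal_cost_curve()].
#' @param target_cost Target cost in percent; must lie within the curve's
#'   achieved range.
#' @return Interpolated parameter value.
#' @export
invert_cost <- function(curve, target_cost) {
  iso <- isoreg(curve$value, curve$cost)
  cost <- iso$yf
  if (target_cost < min(cost) || target_cost > max(cost)) {
    stop("invert_cost: target cost ", target_cost,
         "% outside the achieved range [", round(min(cost), 2), ", ",
         round(max(cost), 2), "]")
  }
  approx(x = cost, y = curve$value, xout = target_cost, ties = "ordered",
         rule = 2)$y
}
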