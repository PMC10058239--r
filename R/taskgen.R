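# Task generation for the three-condition restless two-armed bandit:
# bounded random walks of mean rewards, one-sided excursions, block assembly
# for the volatile (V+) and reference (Ref) conditions, calibration of the
# reward sampling SD, and difficulty matching of the stochastic (S+)
# condition against V+ via a greedy Kalman filter.

#' Moment-matched beta shape parameters on the 1-99 point scale
#'
#' @param mean Mean in points (1 < mean < 99).
#' @param sd SD in points (> 0), must satisfy the beta variance bound.
#' @return A list with vectors `a` and `b`.
#' @keywords internal
beta_shapes <- function(mean, sd) {
  if (any(mean <= 1) || any(mean >= 99)) {
    stop("mean must lie strictly within (1, 99) points")
  }
  if (any(sd <= 0)) stop("sd must be positive")
  mu <- (mean - 1) / 98
  sig2 <- (sd / 98)^2
  nu <- mu * (1 - mu) / sig2 - 1
  if (any(nu <= 0)) {
    stop("(mean, sd) implies invalid beta shape parameters (variance too large)")
  }
  list(a = mu * nu, b = (1 - mu) * nu)
}

#' Sample integer rewards from a moment-matched beta distribution
#'
#' Draws are taken from a beta distribution with the requested mean and SD,
#' scaled to the 1-99 point range, rounded half-up to integers and clipped to
#' \[1, 99\]. `sd = 0` returns the rounded mean.
#'
#' @param mean Mean reward(s) in points; recycled against `n`.
#' @param sd Reward SD in points.
#' @param n Number of draws (defaults to `length(mean)`).
#' @return Integer rewards in \[1, 99\].
#' @export
sample_rewards <- function(mean, sd, n = length(mean)) {
  mean <- rep_len(mean, n)
  if (sd == 0) {
    return(pmin(99L, pmax(1L, as.integer(floor(mean + 0.5)))))
  }
  sh <- beta_shapes(mean, sd)
  draws <- rbeta(n, sh$a, sh$b)
  pmin(99L, pmax(1L, as.integer(floor(1 + 98 * draws + 0.5))))
}

#' Probability that a sampled integer reward exceeds 50 points
#'
#' Exact under the reward model of [sample_rewards()]: an integer reward
#' above 50 corresponds to a continuous draw of at least 50.5 points before
#' rounding.
#'
#' @inheritParams sample_rewards
#' @return Probability of an integer reward > 50.
#' @keywords internal
reward_exceed50_prob <- function(mean, sd) {
  sh <- beta_shapes(mean, sd)
  pbeta((50.5 - 1) / 98, sh$a, sh$b, lower.tail = FALSE)
}

#' Generate a bounded random walk of mean rewards
#'
#' Each step draws the next mean from a beta distribution on the 1-99 point
#' range, moment-matched to be centered on the previous value with SD
#' `step_sd`. Whole walks are rejected and regenerated until every value lies
#' within `bounds` and every absolute step is at most `max_step`.
#'
#' @param n_steps Walk length in trials (>= 1).
#' @param step_sd Drifting SD in points (default 5); `0` gives a constant
#'   walk.
#' @param start Starting mean in points (default 50).
#' @param bounds Admissible range of values (default `c(10, 90)`).
#' @param max_step Maximum absolute step in points (default 10).
#' @param max_attempts Rejection-sampling cap; exceeded attempts are an
#'   error.
#' @return Numeric vector of mean rewards.
#' @export
generate_walk <- function(n_steps = 80, step_sd = 5, start = 50,
                          bounds = c(10, 90), max_step = 10,
                          max_attempts = 1e5) {
  stopifnot(n_steps >= 1, step_sd >= 0, start >= bounds[1], start <= bounds[2])
  if (step_sd == 0) {
    return(rep(start, n_steps))
  }
  for (attempt in seq_len(max_attempts)) {
    w <- raw_walk(n_steps, step_sd, start, bounds, max_step)
    if (!is.null(w)) {
      return(w)
    }
  }
  stop("generate_walk: rejection sampling exceeded ", max_attempts,
       " attempts")
}

# One unconstrained walk attempt; returns NULL as soon as a constraint is
# violated (early exit keeps rejection sampling cheap).
raw_walk <- function(n_steps, step_sd, start, bounds, max_step) {
  v <- numeric(n_steps)
  v[1] <- start
  for (i in seq_len(n_steps - 1L)) {
    sh <- beta_shapes(v[i], step_sd)
    nxt <- 1 + 98 * rbeta(1, sh$a, sh$b)
    if (abs(nxt - v[i]) > max_step || nxt < bounds[1] || nxt > bounds[2]) {
      return(NULL)
    }
    v[i + 1L] <- nxt
  }
  v
}

#' Generate a pool of admissible random walks
#'
#' Generates `n_raw` walk attempts and keeps those satisfying the bound and
#' step constraints, mirroring a generate-then-discard scheme.
#'
#' @param n_raw Number of raw walks to attempt (default 2000).
#' @inheritParams generate_walk
#' @param min_keep Minimum number of surviving walks required.
#' @return A list of numeric vectors.
#' @export
generate_walk_pool <- function(n_raw = 2000, n_steps = 80, step_sd = 5,
                               start = 50, bounds = c(10, 90), max_step = 10,
                               min_keep = 5) {
  pool <- vector("list", n_raw)
  kept <- 0L
  for (i in seq_len(n_raw)) {
    w <- raw_walk(n_steps, step_sd, start, bounds, max_step)
    if (!is.null(w)) {
      kept <- kept + 1L
      pool[[kept]] <- w
    }
  }
  if (kept < min_keep) {
    stop("generate_walk_pool: only ", kept, " of ", n_raw,
         " walks survived the constraints (need ", min_keep, ")")
  }
  pool[seq_len(kept)]
}

# Maximal runs of consecutive values strictly on one side of 50 within one
# walk; returns a data.frame of candidates (start, length, side).
one_sided_runs <- function(walk) {
  side <- ifelse(walk > 50, 1L, ifelse(walk < 50, -1L, 0L))
  r <- rle(side)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values != 0L
  data.frame(start = starts[ok], length = r$lengths[ok],
             side = r$values[ok])
}

#' Extract one-sided excursions from a pool of walks
#'
#' An excursion is a maximal contiguous sub-sequence of a walk lying
#' strictly above or strictly below 50 points (a segment between
#' 50-crossings or walk edges). For each target length, a maximal one-sided
#' run of exactly that length is chosen uniformly at random from the pool.
#'
#' @param walks List of walks (numeric vectors).
#' @param target_lengths Excursion lengths to return (default
#'   `c(8, 12, 16, 20, 24)`).
#' @return A list of excursions, each a list with `values`, `length`, `side`
#'   (`"above"` or `"below"`), and `mean_reward`.
#' @export
extract_excursions <- function(walks, target_lengths = c(8, 12, 16, 20, 24)) {
  runs <- do.call(rbind, lapply(seq_along(walks), function(i) {
    r <- one_sided_runs(walks[[i]])
    if (nrow(r) == 0) return(NULL)
    r$walk <- i
    r
  }))
  if (is.null(runs) || nrow(runs) == 0) {
    stop("extract_excursions: no one-sided segments in the walk pool")
  }
  lapply(target_lengths, function(L) {
    cand <- runs[runs$length == L, , drop = FALSE]
    if (nrow(cand) == 0) {
      stop("extract_excursions: no one-sided segment of length ", L,
           " in the walk pool")
    }
    pick <- cand[sample.int(nrow(cand), 1L), ]
    vals <- walks[[pick$walk]][pick$start:(pick$start + L - 1L)]
    list(values = vals, length = L,
         side = if (pick$side > 0) "above" else "below",
         mean_reward = mean(vals))
  })
}

# Assemble the per-trial schedule data.frame shared by all block builders.
new_block_df <- function(condition, block, mean_1, round_index,
                         reversal_flag, sampling_sd) {
  n <- length(mean_1)
  mean_2 <- 100 - mean_1
  data.frame(condition = condition, block = block, trial = seq_len(n),
             round = round_index, mean_1 = mean_1, mean_2 = mean_2,
             reward_1 = sample_rewards(mean_1, sampling_sd),
             reward_2 = sample_rewards(mean_2, sampling_sd),
             reversal_flag = reversal_flag)
}

#' Build a volatile (V+) block from five excursions
#'
#' Concatenates the excursions in random order with forced side alternation
#' (mirroring values through 50 where needed) so that the two options'
#' generative means cross at every junction; those junctions are the
#' reversals. Option 2's mean is the mirror `100 - mean_1`.
#'
#' @param excursions List of excursions whose lengths sum to 80.
#' @param sampling_sd Reward SD in points.
#' @param block Block index recorded in the output.
#' @param n_trials Required total length (default 80).
#' @return A block data.frame (one row per trial) with columns `condition`,
#'   `block`, `trial`, `round`, `mean_1`, `mean_2`, `reward_1`, `reward_2`,
#'   `reversal_flag`.
#' @export
build_vplus_block <- function(excursions, sampling_sd, block = 1L,
                              n_trials = 80) {
  lens <- vapply(excursions, `[[`, numeric(1), "length")
  if (sum(lens) != n_trials) {
    stop("excursion lengths must sum to ", n_trials, " trials")
  }
  ord <- sample.int(length(excursions))
  excursions <- excursions[ord]
  first_above <- runif(1) < 0.5
  mean_1 <- numeric(0)
  rev_flag <- logical(0)
  for (i in seq_along(excursions)) {
    vals <- excursions[[i]]$values
    want_above <- if (first_above) (i %% 2L == 1L) else (i %% 2L == 0L)
    is_above <- excursions[[i]]$side == "above"
    if (want_above != is_above) vals <- 100 - vals
    flags <- c(i > 1L, rep(FALSE, length(vals) - 1L))
    mean_1 <- c(mean_1, vals)
    rev_flag <- c(rev_flag, flags)
  }
  new_block_df("V+", block, mean_1, round_index = 1L,
               reversal_flag = rev_flag, sampling_sd = sampling_sd)
}

#' Build a reference (Ref) block from five excursions
#'
#' Each excursion's mean reward becomes the static generative mean of one
#' round; excursion sides are preserved and round order is randomized.
#'
#' @inheritParams build_vplus_block
#' @return A block data.frame as in [build_vplus_block()] with `round`
#'   labelling the five rounds.
#' @export
build_ref_block <- function(excursions, sampling_sd, block = 1L,
                            n_trials = 80) {
  lens <- vapply(excursions, `[[`, numeric(1), "length")
  if (sum(lens) != n_trials) {
    stop("excursion lengths must sum to ", n_trials, " trials")
  }
  ord <- sample.int(length(excursions))
  excursions <- excursions[ord]
  mean_1 <- unlist(lapply(excursions, function(e) {
    rep(e$mean_reward, e$length)
  }))
  round_index <- rep(seq_along(excursions),
                     vapply(excursions, `[[`, numeric(1), "length"))
  new_block_df("Ref", block, mean_1, round_index = round_index,
               reversal_flag = FALSE, sampling_sd = sampling_sd)
}

#' Calibrate the reward sampling SD for the Ref condition
#'
#' Finds the single SD such that, pooled over rounds (weighted by round
#' length), 75% of integer rewards sampled from the better option exceed 50
#' points. Solved by root finding on the exact beta tail probability.
#'
#' @param ref_means Better-option round means in points (all > 50).
#' @param weights Round lengths used as pooling weights (default equal).
#' @param target Target exceedance probability (default 0.75).
#' @param interval Search bracket for the SD in points.
#' @param tol Root-finding tolerance on the SD.
#' @return The calibrated SD in points.
#' @export
calibrate_sampling_sd <- function(ref_means, weights = NULL, target = 0.75,
                                  interval = c(0.5, 30), tol = 1e-4) {
  if (any(ref_means <= 50)) {
    stop("calibrate_sampling_sd: all better-option means must exceed 50")
  }
  if (is.null(weights)) weights <- rep(1, length(ref_means))
  weights <- weights / sum(weights)
  # keep the bracket inside the beta-validity region for every mean
  max_valid <- min(98 * sqrt(((ref_means - 1) / 98) * ((99 - ref_means) / 98)))
  hi <- min(interval[2], max_valid * 0.999)
  f <- function(s) {
    sum(weights * reward_exceed50_prob(ref_means, s)) - target
  }
  if (f(interval[1]) < 0 || f(hi) > 0) {
    stop("calibrate_sampling_sd: no SD in the bracket [", interval[1], ", ",
         round(hi, 2), "] reaches the ", target, " target")
  }
  uniroot(f, c(interval[1], hi), tol = tol)$root
}

#' Effective generative variances of a set of blocks
#'
#' The effective sampling variance is the variance of realized rewards around
#' their generative means, pooled over trials and options; the effective
#' drifting variance is the variance of successive generative-mean
#' increments (zero in the static Ref/S+ conditions). Both are reported on
#' the 0-1 rescaled reward scale.
#'
#' @param blocks A block data.frame (one condition; possibly several blocks).
#' @return An `nb_genspec` object with `v_s_eff`, `v_d_eff` and `condition`.
#' @export
compute_effective_variances <- function(blocks) {
  cond <- unique(blocks$condition)
  stopifnot(length(cond) == 1)
  dev <- c(blocks$reward_1 - blocks$mean_1,
           blocks$reward_2 - blocks$mean_2) / 100
  v_s_eff <- var(dev)
  if (cond == "V+") {
    incr <- unlist(lapply(split(blocks$mean_1, blocks$block), diff)) / 100
    v_d_eff <- var(incr)
  } else {
    v_d_eff <- 0
  }
  structure(list(v_s_eff = v_s_eff, v_d_eff = v_d_eff, condition = cond),
            class = "nb_genspec")
}

# Reinitialization points for a block data.frame: each new round in the
# static conditions, each new block in V+ (reversals are covert).
reinit_flags <- function(blocks) {
  n <- nrow(blocks)
  key <- if (all(blocks$condition == "V+")) {
    blocks$block
  } else {
    paste(blocks$block, blocks$round)
  }
  c(TRUE, key[-1] != key[-n])
}

#' Accuracy of the greedy optimal Kalman filter on a schedule
#'
#' Simulates the optimal learning agent (greedy, noise-free, variances set to
#' the supplied effective values) on the generative means of `blocks`,
#' resampling rewards from the generative beta distributions on every run.
#'
#' @param blocks Block data.frame for one condition.
#' @param sampling_sd Reward SD used to resample rewards.
#' @param v_s_eff,v_d_eff Effective variances given to the agent.
#' @param n_sims Number of simulated runs.
#' @return Mean accuracy (fraction of choices of the better option).
#' @export
optimal_accuracy <- function(blocks, sampling_sd, v_s_eff, v_d_eff,
                             n_sims = 10000) {
  sh1 <- beta_shapes(blocks$mean_1, sampling_sd)
  sh2 <- beta_shapes(blocks$mean_2, sampling_sd)
  cpp_accuracy_greedy(blocks$mean_1, blocks$mean_2, reinit_flags(blocks),
                      sh1$a, sh1$b, sh2$a, sh2$b,
                      v_s_eff, v_d_eff, NB_V0, as.integer(n_sims))
}

#' Match the S+ condition's difficulty to the V+ condition
#'
#' Shrinks the Ref blocks' static round means multiplicatively toward 50
#' until the simulated accuracy of the greedy optimal Kalman filter matches
#' the target V+ accuracy within tolerance. The reward sampling SD is left
#' unchanged, so reward variability is unchanged while discriminability
#' falls.
#'
#' @param ref_blocks Ref block data.frame (template for the S+ schedule).
#' @param sampling_sd Reward SD in points.
#' @param vplus_accuracy Target accuracy in (0.5, 1).
#' @param v_s_eff Effective sampling variance given to the evaluating agent.
#' @param shrink_step Multiplicative shrink of `(mean - 50)` per iteration.
#' @param tol Accuracy tolerance.
#' @param n_sims Simulated runs per accuracy evaluation.
#' @param min_dev Error out when the largest |mean - 50| falls below this
#'   (target unreachable).
#' @return The S+ block data.frame, with attributes `accuracy` (achieved)
#'   and `n_iter` (shrink iterations).
#' @export
match_splus_difficulty <- function(ref_blocks, sampling_sd, vplus_accuracy,
                                   v_s_eff, shrink_step = 0.99, tol = 0.005,
                                   n_sims = 10000, min_dev = 0.5) {
  stopifnot(vplus_accuracy > 0.5, vplus_accuracy < 1)
  dev0 <- ref_blocks$mean_1 - 50
  acc_at <- function(j) {
    optimal_accuracy(transform_means(ref_blocks, 50 + dev0 * shrink_step^j),
                     sampling_sd, v_s_eff, 0, n_sims)
  }
  acc <- acc_at(0)
  if (acc < vplus_accuracy - tol) {
    stop("match_splus_difficulty: target accuracy ",
         round(vplus_accuracy, 3), " exceeds the unshrunk Ref accuracy ",
         round(acc, 3))
  }
  # the incremental procedure stops at the first shrink count whose accuracy
  # falls to the target band; accuracy is monotone in the shrink count, so
  # that first count is located by bisection over the same 1%-shrink grid
  n_iter <- 0L
  if (acc > vplus_accuracy + tol) {
    j_max <- floor(log(min_dev / max(abs(dev0))) / log(shrink_step))
    acc_max <- acc_at(j_max)
    if (acc_max > vplus_accuracy + tol) {
      stop("match_splus_difficulty: means reached 50 before matching the ",
           "target accuracy")
    }
    lo <- 0L; hi <- as.integer(j_max); acc <- acc_max
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      a <- acc_at(mid)
      if (a > vplus_accuracy + tol) {
        lo <- mid
      } else {
        hi <- mid
        acc <- a
      }
    }
    n_iter <- hi
  }
  out <- transform_means(ref_blocks, 50 + dev0 * shrink_step^n_iter)
  out$condition <- "S+"
  out$reward_1 <- sample_rewards(out$mean_1, sampling_sd)
  out$reward_2 <- sample_rewards(out$mean_2, sampling_sd)
  attr(out, "accuracy") <- acc
  attr(out, "n_iter") <- n_iter
  out
}

# Replace generative means in a block data.frame, keeping structure.
transform_means <- function(blocks, mean_1) {
  blocks$mean_1 <- mean_1
  blocks$mean_2 <- 100 - mean_1
  blocks
}

#' Generate a complete matched task set (Ref, S+, V+)
#'
#' Runs the full schedule-generation procedure: draw a pool of bounded
#' random walks, extract five one-sided excursions per block, assemble V+
#' blocks (drifting means with forced reversals) and Ref blocks (each
#' excursion's mean as a static round mean), calibrate the reward SD so 75%
#' of better-option Ref rewards exceed 50 points, and derive the S+ blocks
#' by shrinking the Ref means toward 50 until greedy Kalman-filter accuracy
#' matches the V+ condition.
#'
#' @param n_blocks Blocks per condition (default 2).
#' @param n_trials Trials per block (default 80).
#' @param n_raw_walks Raw walks per pool (default 2000).
#' @param match_n_sims Simulated runs per difficulty-matching evaluation.
#' @param match_tol Accuracy tolerance for difficulty matching.
#' @return An `nb_taskset` list: `blocks` (all conditions), `sampling_sd`,
#'   `genspec` (per condition), `vplus_accuracy`, `match_iter`.
#' @export
generate_task_set <- function(n_blocks = 2, n_trials = 80, n_raw_walks = 2000,
                              match_n_sims = 10000, match_tol = 0.005) {
  target_lengths <- c(8, 12, 16, 20, 24)
  pool <- generate_walk_pool(n_raw = n_raw_walks, n_steps = n_trials)
  # the step-size and bound constraints reject ~99% of raw walks; extend the
  # pool until every excursion length has an exact-length one-sided run
  lengths_present <- function(p) {
    lens <- unlist(lapply(p, function(w) one_sided_runs(w)$length))
    all(target_lengths %in% lens)
  }
  extensions <- 0L
  while (!lengths_present(pool) && extensions < 40L) {
    pool <- c(pool, generate_walk_pool(n_raw = n_raw_walks,
                                       n_steps = n_trials))
    extensions <- extensions + 1L
  }
  exc_per_block <- lapply(seq_len(n_blocks), function(b) {
    extract_excursions(pool)
  })
  ref_means <- unlist(lapply(exc_per_block, function(exc) {
    vapply(exc, `[[`, numeric(1), "mean_reward")
  }))
  lens <- unlist(lapply(exc_per_block, function(exc) {
    vapply(exc, `[[`, numeric(1), "length")
  }))
  better <- pmax(ref_means, 100 - ref_means)
  sampling_sd <- calibrate_sampling_sd(better, weights = lens)
  ref <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    build_ref_block(exc_per_block[[b]], sampling_sd, block = b,
                    n_trials = n_trials)
  }))
  vplus <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    build_vplus_block(exc_per_block[[b]], sampling_sd, block = b,
                      n_trials = n_trials)
  }))
  spec_ref <- compute_effective_variances(ref)
  spec_vplus <- compute_effective_variances(vplus)
  vplus_acc <- optimal_accuracy(vplus, sampling_sd, spec_vplus$v_s_eff,
                                spec_vplus$v_d_eff, n_sims = match_n_sims)
  splus <- match_splus_difficulty(ref, sampling_sd, vplus_acc,
                                  spec_ref$v_s_eff, tol = match_tol,
                                  n_sims = match_n_sims)
  spec_splus <- compute_effective_variances(splus)
  blocks <- rbind(ref, splus, vplus)
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, sampling_sd = sampling_sd,
                 genspec = list("Ref" = spec_ref, "S+" = spec_splus,
                                "V+" = spec_vplus),
                 vplus_accuracy = vplus_acc,
                 match_iter = attr(splus, "n_iter")),
            class = "nb_taskset")
}

#' Replicate a schedule with fresh reward draws
#'
#' Stacks `n_rep` copies of a block schedule, redrawing the realized rewards
#' of both options from their generative means on every copy (block ids are
#' shifted to keep copies distinct). Useful wherever a quantity is averaged
#' over reward realizations rather than conditioned on one draw — e.g. the
#' reward-excess baselines of cost curves, which are fragile on a single
#' realization of a hard schedule.
#'
#' @param blocks Block data.frame for one condition.
#' @param sampling_sd Reward SD in points.
#' @param n_rep Number of copies.
#' @return A block data.frame with `n_rep * length(unique(block))` blocks.
#' @export
replicate_block_rewards <- function(blocks, sampling_sd, n_rep = 10) {
  n_blocks <- length(unique(blocks$block))
  out <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    b <- blocks
    b$block <- b$block + (i - 1L) * n_blocks
    b$reward_1 <- sample_rewards(b$mean_1, sampling_sd)
    b$reward_2 <- sample_rewards(b$mean_2, sampling_sd)
    b
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.nb_taskset <- function(x, ...) {
  cat("<nb_taskset>", nrow(x$blocks), "trials;",
      sprintf("sampling_sd=%.2f pts; V+ optimal accuracy=%.3f (matched in %d iters)\n",
              x$sampling_sd, x$vplus_accuracy, x$match_iter))
  invisible(x)
}
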