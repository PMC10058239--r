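# Orchestration: study configuration, the exclusion rule and bonus
# threshold (exact binomial computations), and the end-to-end synthetic
# study (generate -> simulate -> fit -> select -> recover -> costs ->
# stats).

#' Accuracy bound for above-chance performance
#'
#' The largest accuracy NOT in the one-tailed rejection region of an exact
#' binomial test against chance (p = 0.5): a subject must strictly exceed
#' this bound to perform significantly above chance. The bound never falls
#' below 0.5.
#'
#' @param n_trials Number of trials.
#' @param alpha One-tailed significance level (default 0.05).
#' @return The accuracy bound as a fraction.
#' @export
bonus_threshold <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1, alpha > 0, alpha <= 1)
  # smallest count whose upper tail P(X >= c) is at most alpha
  tails <- pbinom(0:n_trials - 1, n_trials, 0.5, lower.tail = FALSE)
  idx <- which(tails <= alpha)
  crit <- if (length(idx) == 0) n_trials + 1 else min(idx) - 1
  max(0.5, (crit - 1) / n_trials)
}

#' Above-chance test for one accuracy count
#'
#' One-tailed exact binomial test of `k` correct out of `n` against chance.
#'
#' @param k Correct choices.
#' @param n Trials.
#' @param alpha One-tailed level.
#' @return `TRUE` when performance significantly exceeds chance.
#' @keywords internal
above_chance <- function(k, n, alpha = 0.05) {
  pbinom(k - 1, n, 0.5, lower.tail = FALSE) <= alpha
}

#' Exclude subjects not above chance in every condition
#'
#' Applies the one-tailed exact binomial test against 50% accuracy per
#' condition; a subject is kept only if significant in all conditions.
#'
#' @param sessions Session data.frame with `subject`, `condition`,
#'   `correct`.
#' @param alpha One-tailed level (default 0.05).
#' @return A list with `kept` and `excluded` subject ids and a per-subject
#'   `table` (condition counts and decisions).
#' @export
exclusion_filter <- function(sessions, alpha = 0.05) {
  tab <- do.call(rbind, lapply(split(sessions,
                                     list(sessions$subject,
                                          sessions$condition),
                                     drop = TRUE), function(s) {
    data.frame(subject = s$subject[1], condition = s$condition[1],
               n = nrow(s), k = sum(s$correct))
  }))
  tab$pass <- above_chance(tab$k, tab$n, alpha)
  keep <- tapply(tab$pass, tab$subject, all)
  kept <- as.integer(names(keep))[keep]
  excluded <- as.integer(names(keep))[!keep]
  rownames(tab) <- NULL
  list(kept = sort(kept), excluded = sort(excluded), table = tab)
}

#' Study configuration
#'
#' Collects every knob of the end-to-end synthetic study. Defaults are desk
#' scale; the per-stage seeds are derived from `seed` as fixed offsets so
#' every random stage receives its own named substream.
#'
#' @param n_subjects Cohort size.
#' @param n_blocks Blocks per condition.
#' @param population Population spec for the cohort.
#' @param task_per_subject Fresh task set per subject.
#' @param match_n_sims Difficulty-matching simulations per evaluation.
#' @param fit Named list of fitting settings (`n_particles`, `n_restarts`,
#'   `maxit`).
#' @param run_bms Run the three-model comparison (slower).
#' @param cost_grid_zeta,cost_grid_tau Cost-curve grids (must start at 0).
#' @param cost_n_sims Simulated traversals per cost grid point.
#' @param n_boot Bootstrap resamples for the PCA stage.
#' @param seed Master seed.
#' @return An `nb_config` list.
#' @export
study_config <- function(n_subjects = 30, n_blocks = 2,
                         population = population_spec(),
                         task_per_subject = TRUE, match_n_sims = 10000,
                         fit = list(n_particles = 500, n_restarts = 4,
                                    maxit = 200),
                         run_bms = FALSE,
                         cost_grid_zeta = seq(0, 1.5, length.out = 16),
                         cost_grid_tau = seq(0, 0.5, length.out = 16),
                         cost_n_sims = 2000, n_boot = 1000, seed = 1L) {
  structure(as.list(environment()), class = "nb_config")
}

# Polynomial rolling hash of the serialized config (mod 2^31 - 1, exact in
# double arithmetic), for provenance stamping.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% (2^31 - 1)
  }
  sprintf("%08x", as.integer(h))
}

#' Run the synthetic study end to end
#'
#' Executes every stage from one configuration and master seed: task and
#' cohort generation, the exclusion filter, per-subject full-model fits,
#' optional three-model Bayesian model selection, parameter recovery against
#' ground truth, marginal cost curves per condition at the cohort's median
#' fitted parameters, the 12 x 12 parameter correlation matrix, and PCA.
#' Rerunning with the same configuration reproduces all numbers.
#'
#' @param config An `nb_config` from [study_config()].
#' @param verbose Print per-stage progress.
#' @return An `nb_report` list of stage outputs plus a `provenance` block
#'   (config, hash, seed, package version).
#' @export
run_study <- function(config = study_config(), verbose = TRUE) {
  stopifnot(inherits(config, "nb_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage_seed <- function(offset) as.integer((config$seed + offset) %% 2^31)

  say("[cohort] generating %d subjects", config$n_subjects)
  set.seed(stage_seed(101))
  cohort <- generate_synthetic_cohort(
    config$n_subjects, population = config$population,
    task_per_subject = config$task_per_subject, n_blocks = config$n_blocks,
    match_n_sims = config$match_n_sims)

  say("[exclusion] binomial filter")
  excl <- exclusion_filter(cohort$sessions)
  sessions <- cohort$sessions[cohort$sessions$subject %in% excl$kept, ]

  say("[behavior] summaries and aligned curves")
  behavior <- do.call(rbind, lapply(split(sessions,
                                          list(sessions$subject,
                                               sessions$condition),
                                          drop = TRUE), function(s) {
    sm <- summarize_session(s)
    data.frame(subject = s$subject[1], condition = s$condition[1],
               accuracy = sm$accuracy, switch_rate = sm$switch_rate)
  }))
  rownames(behavior) <- NULL
  curves <- lapply(setNames(NB_CONDITIONS, NB_CONDITIONS), function(cond) {
    sub <- sessions[sessions$condition == cond, ]
    aligned_curves(sub, align = if (cond == "V+") "reversal" else
      "round_start")
  })

  say("[fit] full model, %d subjects x 3 conditions", length(excl$kept))
  set.seed(stage_seed(202))
  fits <- fit_cohort(sessions, model = "full",
                     n_particles = config$fit$n_particles,
                     n_restarts = config$fit$n_restarts,
                     maxit = config$fit$maxit, seed = stage_seed(203))

  bms_result <- NULL
  if (isTRUE(config$run_bms)) {
    say("[bms] three-model comparison")
    set.seed(stage_seed(303))
    models <- c("full", "nozeta", "notau")
    ev <- matrix(NA_real_, 0, 3, dimnames = list(NULL, models))
    i <- 0L
    for (s in excl$kept) {
      for (cond in NB_CONDITIONS) {
        i <- i + 1L
        ses <- sessions[sessions$subject == s &
                          sessions$condition == cond, ]
        row <- vapply(models, function(m) {
          fit <- fit_subject(ses, model = m,
                             n_particles = config$fit$n_particles,
                             n_restarts = config$fit$n_restarts,
                             maxit = config$fit$maxit,
                             seed = stage_seed(304) + i)
          evidence_proxy(fit)
        }, numeric(1))
        ev <- rbind(ev, row)
      }
    }
    bms_result <- bms(ev)
  }

  say("[recovery] generating vs recovered parameters")
  recovery <- parameter_recovery(
    cohort$truth[cohort$truth$subject %in% excl$kept, ], fits)

  say("[costs] marginal cost curves at cohort median parameters")
  set.seed(stage_seed(404))
  cost_curves <- list()
  for (cond in NB_CONDITIONS) {
    med <- apply(fits[fits$condition == cond,
                      c("alpha", "zeta", "delta", "tau")], 2, median)
    base <- agent_params(alpha = med[["alpha"]], zeta = med[["zeta"]],
                         delta = med[["delta"]], tau = med[["tau"]])
    ts1 <- cohort$task_sets[[1]]
    blocks <- ts1$blocks[ts1$blocks$condition == cond, ]
    # pool over fresh reward realizations so the zero-variability baseline
    # excess is estimated stably even in the hardest condition
    blocks <- replicate_block_rewards(blocks, ts1$sampling_sd, n_rep = 10)
    n_sims <- max(1L, config$cost_n_sims %/% 10L)
    cost_curves[[cond]] <- list(
      zeta = marginal_cost_curve(base, "zeta", config$cost_grid_zeta,
                                 blocks, n_sims = n_sims),
      tau = marginal_cost_curve(base, "tau", config$cost_grid_tau, blocks,
                                n_sims = n_sims))
  }

  say("[stats] correlation matrix and PCA")
  set.seed(stage_seed(505))
  pm <- param_matrix(fits)
  corr <- if (nrow(pm) >= 10) param_corr_matrix(pm) else NULL
  pca <- if (nrow(pm) >= 20) pca_params(pm, n_boot = config$n_boot) else NULL

  structure(list(cohort = cohort, exclusion = excl, behavior = behavior,
                 curves = curves, fits = fits, bms = bms_result,
                 recovery = recovery, cost_curves = cost_curves,
                 corr = corr, pca = pca,
                 provenance = list(config = config,
                                   config_hash = config_hash(config),
                                   seed = config$seed,
                                   package_version =
                                     as.character(utils::packageVersion("noisybandit")))),
            class = "nb_report")
}

#' @export
print.nb_report <- function(x, ...) {
  cat("<nb_report>", nrow(x$behavior), "subject x condition summaries;",
      "config", x$provenance$config_hash, "\n")
  invisible(x)
}
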