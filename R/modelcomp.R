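# Model comparison: penalized-likelihood evidence, random-effects Bayesian
# model selection over the full model and its reduced variants (zeta = 0,
# tau = 0), and model / parameter recovery.

#' Penalized log-likelihood model evidence
#'
#' Information-criterion proxy for per-subject model evidence:
#' `loglik - (k / 2) * log(n)` with `k` free parameters and `n` observed
#' choices (the BIC divided by -2).
#'
#' @param fit An `nb_fit` from [fit_subject()], or a list with `loglik`,
#'   `model` and `n_trials`.
#' @param n_trials Number of choices; defaults to `fit$n_trials`.
#' @return Log-evidence proxy in nats.
#' @export
evidence_proxy <- function(fit, n_trials = fit$n_trials) {
  k <- length(free_params(fit$model))
  fit$loglik - (k / 2) * log(n_trials)
}

#' Random-effects Bayesian model selection
#'
#' Variational update of a Dirichlet distribution over population model
#' frequencies: subject-wise model responsibilities and Dirichlet
#' pseudo-counts are iterated to convergence from a uniform prior
#' (`alpha0 = 1` per model). Exceedance probabilities (the posterior
#' probability that each model is the most frequent) are computed
#' analytically through the Beta distribution for two models and by
#' Monte-Carlo sampling from the fitted Dirichlet otherwise.
#'
#' @param evidence Numeric matrix of log-evidence values, subjects x models
#'   (column names label the models).
#' @param alpha0 Dirichlet prior pseudo-count per model.
#' @param tol Convergence tolerance on the pseudo-counts.
#' @param max_iter Iteration cap.
#' @param n_samples Monte-Carlo draws for exceedance when K > 2.
#' @return An `nb_bms` list: `alpha` (pseudo-counts), `expected_freq`,
#'   `exceedance`, `responsibilities`.
#' @export
bms <- function(evidence, alpha0 = 1, tol = 1e-6, max_iter = 1000,
                n_samples = 1e5) {
  evidence <- as.matrix(evidence)
  if (!all(is.finite(evidence))) stop("bms: non-finite evidence values")
  n <- nrow(evidence); K <- ncol(evidence)
  stopifnot(n >= 1, K >= 2)
  models <- colnames(evidence)
  if (is.null(models)) models <- paste0("m", seq_len(K))
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  xp <- exceedance_prob(alpha, n_samples = n_samples)
  structure(list(alpha = setNames(alpha, models),
                 expected_freq = setNames(alpha / sum(alpha), models),
                 exceedance = setNames(xp, models),
                 responsibilities = u),
            class = "nb_bms")
}

#' Exceedance probabilities of a Dirichlet distribution
#'
#' Probability that each component has the largest frequency under
#' `Dirichlet(alpha)`. Exact (via the Beta CDF) for two components;
#' Monte-Carlo otherwise.
#'
#' @param alpha Dirichlet parameters.
#' @param n_samples Monte-Carlo draws for K > 2.
#' @return Probabilities summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e5) {
  K <- length(alpha)
  if (K == 2) {
    p1 <- pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(p1, 1 - p1))
  }
  g <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              nrow = n_samples)
  win <- max.col(g, ties.method = "random")
  tabulate(win, nbins = K) / n_samples
}

#' @export
print.nb_bms <- function(x, ...) {
  cat("<nb_bms>\n")
  print(round(rbind(expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

#' Model recovery over the candidate model set
#'
#' For each generating model (full, zeta = 0, tau = 0), simulates a cohort
#' from that model, fits all three candidate models to every subject's
#' session, and runs random-effects model selection. The confusion matrix
#' row for a generating model is the exceedance-probability vector over
#' fitted models, so rows sum to 1 and diagonal dominance means the
#' generating model is identified.
#'
#' @param n_subjects Subjects per generating cohort.
#' @param population Population spec for the generating parameters.
#' @param condition Task condition whose sessions are fitted (default Ref).
#' @param task_set Optional pre-generated `nb_taskset` shared by all
#'   cohorts; generated if `NULL`.
#' @param n_reward_reps Copies of the condition schedule (fresh reward
#'   draws) per subject session. The penalized-likelihood evidence proxy
#'   penalizes the extra parameter of the full model more strongly than a
#'   Bayesian evidence would when that parameter is weakly identified, so
#'   the default recovery study lengthens sessions (3 copies of 2 blocks =
#'   480 trials) to keep the candidate models distinguishable.
#' @param n_particles,n_restarts,maxit Fitting settings (reduced defaults
#'   for recovery studies).
#' @param seed Base seed for fitting.
#' @return An `nb_recovery` list: `confusion` (3 x 3 matrix), `evidence`
#'   (per generating model), `fits`, `truth`.
#' @export
model_recovery <- function(n_subjects = 8,
                           population = population_spec("strong"),
                           condition = "Ref", task_set = NULL,
                           n_reward_reps = 3,
                           n_particles = 500, n_restarts = 4, maxit = 250,
                           seed = 1L) {
  models <- c("full", "nozeta", "notau")
  if (is.null(task_set)) {
    task_set <- generate_task_set(match_n_sims = 5000)
  }
  blocks <- task_set$blocks[task_set$blocks$condition == condition, ]
  if (n_reward_reps > 1) {
    blocks <- replicate_block_rewards(blocks, task_set$sampling_sd,
                                      n_reward_reps)
  }
  confusion <- matrix(NA_real_, 3, 3, dimnames = list(models, models))
  evidence_all <- list()
  fits_all <- list()
  truth_all <- list()
  for (gi in seq_along(models)) {
    gen <- models[gi]
    truth <- draw_cohort_params(n_subjects, population)
    truth <- truth[truth$condition == condition, ]
    if (gen == "nozeta") truth$zeta <- 0
    if (gen == "notau") truth$tau <- 0
    ev <- matrix(NA_real_, n_subjects, 3, dimnames = list(NULL, models))
    for (s in seq_len(n_subjects)) {
      row <- truth[truth$subject == s, ]
      pars <- agent_params(alpha = row$alpha, zeta = row$zeta,
                           delta = row$delta, tau = row$tau)
      ses <- run_session(pars, blocks)
      for (m in models) {
        fit <- fit_subject(ses, model = m, n_particles = n_particles,
                           n_restarts = n_restarts, maxit = maxit,
                           seed = seed + 1000L * gi + 10L * s +
                             match(m, models))
        ev[s, m] <- evidence_proxy(fit)
        fits_all[[length(fits_all) + 1L]] <-
          data.frame(generating = gen, subject = s, model = m,
                     alpha = fit$params_hat$alpha, zeta = fit$params_hat$zeta,
                     delta = fit$params_hat$delta, tau = fit$params_hat$tau,
                     loglik = fit$loglik)
      }
    }
    res <- bms(ev)
    confusion[gen, ] <- res$exceedance
    evidence_all[[gen]] <- ev
    truth$generating <- gen
    truth_all[[gen]] <- truth
  }
  structure(list(confusion = confusion, evidence = evidence_all,
                 fits = do.call(rbind, fits_all),
                 truth = do.call(rbind, truth_all)),
            class = "nb_recovery")
}

#' Parameter recovery summary
#'
#' Spearman rank correlation and median signed error between generating and
#' recovered parameter values, matched by subject (and condition when
#' present).
#'
#' @param truth Ground-truth parameter data.frame (`subject`, optionally
#'   `condition`, `alpha`, `zeta`, `delta`, `tau`).
#' @param fits Fitted parameter data.frame in the same format.
#' @return A data.frame with one row per parameter: `parameter`, `rho`,
#'   `p_value`, `median_bias`, `n`.
#' @export
parameter_recovery <- function(truth, fits) {
  keys <- intersect(c("subject", "condition"), names(truth))
  merged <- merge(truth, fits, by = keys, suffixes = c("_true", "_hat"))
  if (nrow(merged) != nrow(truth)) {
    stop("parameter_recovery: truth and fits tables do not match")
  }
  out <- lapply(c("alpha", "zeta", "delta", "tau"), function(p) {
    x <- merged[[paste0(p, "_true")]]
    y <- merged[[paste0(p, "_hat")]]
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(parameter = p, rho = unname(ct$estimate),
               p_value = ct$p.value, median_bias = median(y - x),
               n = length(x))
  })
  do.call(rbind, out)
}
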