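# Synthetic cohorts: population distributions over agent parameters, draws
# with cross-condition and between-parameter dependence, simulated sessions,
# and plain-text interchange (CSV) of blocks, truth and sessions.

#' Population distributions for synthetic cohorts
#'
#' Defines per-parameter, per-condition population distributions on latent
#' Gaussian scales: `alpha` and `delta` are logit-normal, `zeta` and `tau`
#' are log-normal. Subjects share a latent factor per parameter across
#' conditions (correlation `r_cond`), and the latent factors of `zeta` and
#' `tau` are correlated with the `alpha` factor (`rho_zeta_alpha`,
#' `rho_tau_alpha`), emulating the observed covariation of learning noise
#' and choice temperature with learning rate. The `"recovery"` kind uses
#' wider, condition-constant distributions spanning the fitting bounds, for
#' parameter- and model-recovery studies.
#'
#' @param kind `"default"` (cohort emulating adaptive condition effects),
#'   `"recovery"` (wide, condition-constant, for parameter-recovery
#'   studies), or `"strong"` (condition-constant with clearly expressed
#'   learning noise and exploration, for model-recovery studies where the
#'   generating sources must be distinguishable).
#' @param r_cond Cross-condition correlation of each parameter's latent
#'   factor.
#' @param rho_zeta_alpha,rho_tau_alpha Latent correlations of learning noise
#'   and choice temperature with learning rate.
#' @return An `nb_population` list of per-parameter specs.
#' @export
population_spec <- function(kind = c("default", "recovery", "strong"),
                            r_cond = 0.5,
                            rho_zeta_alpha = -0.4, rho_tau_alpha = 0.4) {
  kind <- match.arg(kind)
  loc <- function(ref, splus, vplus) c("Ref" = ref, "S+" = splus, "V+" = vplus)
  if (kind == "default") {
    spec <- list(
      alpha = list(dist = "logitnormal",
                   location = loc(qlogis(0.25), qlogis(0.25), qlogis(0.45)),
                   scale = 0.7),
      zeta = list(dist = "lognormal",
                  location = loc(log(0.45), log(0.45), log(0.32)),
                  scale = 0.5),
      delta = list(dist = "logitnormal",
                   location = loc(qlogis(0.35), qlogis(0.35), qlogis(0.35)),
                   scale = 0.7),
      tau = list(dist = "lognormal",
                 location = loc(log(0.055), log(0.055), log(0.085)),
                 scale = 0.5))
  } else if (kind == "recovery") {
    spec <- list(
      alpha = list(dist = "logitnormal",
                   location = loc(0, 0, 0), scale = 1.3),
      zeta = list(dist = "lognormal",
                  location = loc(log(0.35), log(0.35), log(0.35)),
                  scale = 0.8),
      delta = list(dist = "logitnormal",
                   location = loc(qlogis(0.35), qlogis(0.35), qlogis(0.35)),
                   scale = 1.3),
      tau = list(dist = "lognormal",
                 location = loc(log(0.08), log(0.08), log(0.08)),
                 scale = 0.9))
  } else {
    spec <- list(
      alpha = list(dist = "logitnormal",
                   location = loc(0, 0, 0), scale = 1.0),
      zeta = list(dist = "lognormal",
                  location = loc(log(1.1), log(1.1), log(1.1)),
                  scale = 0.3),
      delta = list(dist = "logitnormal",
                   location = loc(qlogis(0.3), qlogis(0.3), qlogis(0.3)),
                   scale = 0.8),
      tau = list(dist = "lognormal",
                 location = loc(log(0.07), log(0.07), log(0.07)),
                 scale = 0.3))
  }
  structure(list(params = spec, r_cond = r_cond,
                 rho_zeta_alpha = rho_zeta_alpha,
                 rho_tau_alpha = rho_tau_alpha, kind = kind),
            class = "nb_population")
}

# Back-transform a latent Gaussian draw into parameter space, clamped to the
# fitting bounds.
latent_to_param <- function(param, latent, spec, condition) {
  s <- spec$params[[param]]
  z <- s$location[[condition]] + s$scale * latent
  val <- switch(s$dist,
    lognormal = exp(z),
    logitnormal = plogis(z),
    stop("unknown population distribution: ", s$dist))
  b <- param_bounds()[[param]]
  pmin(b[2], pmax(b[1], val))
}

# Fitting bounds shared by the population generator and the optimizer.
param_bounds <- function() {
  list(alpha = c(0.001, 0.999), zeta = c(0, 2), delta = c(0, 1),
       tau = c(1e-4, 1))
}

#' Draw ground-truth parameters for a synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param population An `nb_population` from [population_spec()].
#' @return A data.frame with one row per subject x condition and columns
#'   `subject`, `condition`, `alpha`, `zeta`, `delta`, `tau`.
#' @export
draw_cohort_params <- function(n_subjects, population = population_spec()) {
  stopifnot(inherits(population, "nb_population"))
  rows <- vector("list", n_subjects)
  r_cc <- population$r_cond
  for (s in seq_len(n_subjects)) {
    g_alpha <- rnorm(1)
    g_zeta <- population$rho_zeta_alpha * g_alpha +
      sqrt(1 - population$rho_zeta_alpha^2) * rnorm(1)
    g_tau <- population$rho_tau_alpha * g_alpha +
      sqrt(1 - population$rho_tau_alpha^2) * rnorm(1)
    g_delta <- rnorm(1)
    g <- c(alpha = g_alpha, zeta = g_zeta, delta = g_delta, tau = g_tau)
    per_cond <- lapply(NB_CONDITIONS, function(cond) {
      vals <- vapply(names(g), function(p) {
        latent <- sqrt(r_cc) * g[[p]] + sqrt(1 - r_cc) * rnorm(1)
        latent_to_param(p, latent, population, cond)
      }, numeric(1))
      data.frame(subject = s, condition = cond, alpha = vals[["alpha"]],
                 zeta = vals[["zeta"]], delta = vals[["delta"]],
                 tau = vals[["tau"]])
    })
    rows[[s]] <- do.call(rbind, per_cond)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort of noisy Kalman-filter agents
#'
#' Draws per-subject, per-condition ground-truth parameters from the
#' population, generates task schedules, and simulates each subject's
#' sessions (by default 2 blocks of 80 trials per condition). With
#' `task_per_subject = TRUE` every subject receives a freshly generated,
#' difficulty-matched task set; otherwise one task set is shared.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param population An `nb_population` from [population_spec()].
#' @param task_per_subject Generate a task set per subject (default `TRUE`).
#' @param n_blocks Blocks per condition.
#' @param match_n_sims Simulated runs per difficulty-matching evaluation
#'   (passed to [generate_task_set()]).
#' @return An `nb_cohort` list: `truth` (parameter data.frame), `sessions`
#'   (per-trial records with a `subject` column), `task_sets` (list, one per
#'   subject or a single shared set), `population`.
#' @export
generate_synthetic_cohort <- function(n_subjects,
                                      population = population_spec(),
                                      task_per_subject = TRUE, n_blocks = 2,
                                      match_n_sims = 10000) {
  truth <- draw_cohort_params(n_subjects, population)
  shared <- if (!task_per_subject) {
    generate_task_set(n_blocks = n_blocks, match_n_sims = match_n_sims)
  }
  task_sets <- vector("list", n_subjects)
  sessions <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ts <- if (task_per_subject) {
      generate_task_set(n_blocks = n_blocks, match_n_sims = match_n_sims)
    } else {
      shared
    }
    task_sets[[s]] <- ts
    per_cond <- lapply(NB_CONDITIONS, function(cond) {
      row <- truth[truth$subject == s & truth$condition == cond, ]
      pars <- agent_params(alpha = row$alpha, zeta = row$zeta,
                           delta = row$delta, tau = row$tau)
      ses <- run_session(pars, ts$blocks[ts$blocks$condition == cond, ])
      ses$subject <- s
      ses
    })
    sessions[[s]] <- do.call(rbind, per_cond)
  }
  sessions <- do.call(rbind, sessions)
  rownames(sessions) <- NULL
  structure(list(truth = truth, sessions = sessions, task_sets = task_sets,
                 population = population),
            class = "nb_cohort")
}

#' @export
print.nb_cohort <- function(x, ...) {
  cat("<nb_cohort>", length(unique(x$truth$subject)), "subjects,",
      nrow(x$sessions), "trial records\n")
  invisible(x)
}

#' Write / read per-trial session records as CSV
#'
#' @param sessions Session data.frame (with `subject` column).
#' @param path CSV path.
#' @return `read_sessions_csv()` returns the session data.frame.
#' @export
write_sessions_csv <- function(sessions, path) {
  write.csv(sessions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$switch <- as.logical(out$switch)
  out$correct <- as.logical(out$correct)
  out$reversal_flag <- as.logical(out$reversal_flag)
  out
}

#' Write / read block schedules as CSV
#'
#' @param blocks Block data.frame.
#' @param path CSV path.
#' @return `read_blocks_csv()` returns the block data.frame.
#' @export
write_blocks_csv <- function(blocks, path) {
  write.csv(blocks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks_csv
#' @export
read_blocks_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$reversal_flag <- as.logical(out$reversal_flag)
  out
}

#' Write / read ground-truth or fitted parameter tables as CSV
#'
#' @param params Parameter data.frame (`subject`, `condition`, `alpha`,
#'   `zeta`, `delta`, `tau`, plus any diagnostics).
#' @param path CSV path.
#' @return `read_params_csv()` returns the data.frame.
#' @export
write_params_csv <- function(params, path) {
  write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
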