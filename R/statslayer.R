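# Statistical layer: rank correlations and partial rank correlations, FDR
# control, the 12 x 12 parameter correlation matrix with its shuffle null,
# median splits, PCA of standardized parameters with bootstrap CIs and a
# shuffle null, and the analytic power calculation for a target correlation.

#' Spearman rank correlation with p value
#'
#' Thin wrapper around [stats::cor.test()] (method `"spearman"`, two-sided,
#' tie-corrected via the normal approximation in the presence of ties).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("spearman_cor: constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, then computes the partial Pearson
#' correlation of the ranks of `x` and `y` given the ranks of `z`
#' (residualizing both on `z` by least squares). The p value uses the
#' t-distribution with `n - 2 - ncol(z)` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param z Numeric vector or matrix of controls.
#' @return A list with `rho` and `p_value`.
#' @export
partial_spearman <- function(x, y, z) {
  z <- as.matrix(z)
  n <- length(x)
  stopifnot(length(y) == n, nrow(z) == n, n >= 4)
  if (sd(x) == 0 || sd(y) == 0) stop("partial_spearman: constant input")
  rx <- rank(x); ry <- rank(y)
  rz <- apply(z, 2, rank)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  if (sd(ex) == 0 || sd(ey) == 0) {
    return(list(rho = 0, p_value = 1))
  }
  r <- cor(ex, ey)
  df <- n - 2 - ncol(z)
  tval <- r * sqrt(df / (1 - r^2))
  list(rho = r, p_value = 2 * pt(-abs(tval), df))
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' @param pvals P values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejections.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH") <= q
}

#' Subjects x (parameter, condition) matrix from a fitted-parameter table
#'
#' Reshapes a long parameter table (one row per subject x condition) into
#' the wide 12-column matrix (4 parameters x 3 conditions) used for the
#' correlation-matrix and PCA analyses.
#'
#' @param fits Data.frame with `subject`, `condition`, `alpha`, `zeta`,
#'   `delta`, `tau`.
#' @param standardize Scale columns to zero mean / unit variance.
#' @return A numeric matrix with rownames = subjects and column names
#'   `parameter_condition`.
#' @export
param_matrix <- function(fits, standardize = FALSE) {
  params <- c("alpha", "zeta", "delta", "tau")
  conds <- intersect(NB_CONDITIONS, unique(fits$condition))
  subjects <- sort(unique(fits$subject))
  out <- matrix(NA_real_, length(subjects), length(params) * length(conds),
                dimnames = list(subjects, outer(params, conds, paste,
                                                sep = "_")))
  for (cond in conds) {
    sub <- fits[fits$condition == cond, ]
    sub <- sub[match(subjects, sub$subject), ]
    for (p in params) {
      out[, paste(p, cond, sep = "_")] <- sub[[p]]
    }
  }
  if (anyNA(out)) stop("param_matrix: missing subject x condition cells")
  if (standardize) out <- scale(out)
  out
}

#' Pairwise Spearman correlation matrix with FDR flags
#'
#' Computes the correlation matrix of model parameters across subjects and
#' flags the off-diagonal tests significant after Benjamini-Hochberg
#' correction over the 66 unique pairs.
#'
#' @param pm Subjects x parameters matrix from [param_matrix()].
#' @param q FDR level.
#' @return A list with `rho` (symmetric, unit diagonal), `p` (p values),
#'   `significant` (logical matrix after FDR).
#' @export
param_corr_matrix <- function(pm, q = 0.05) {
  stopifnot(nrow(pm) >= 10)
  k <- ncol(pm)
  rho <- diag(1, k); pmat <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(pmat) <- list(colnames(pm), colnames(pm))
  pair_p <- c(); pair_idx <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- spearman_cor(pm[, i], pm[, j])
      rho[i, j] <- rho[j, i] <- ct$rho
      pmat[i, j] <- pmat[j, i] <- ct$p_value
      pair_p <- c(pair_p, ct$p_value)
      pair_idx[[length(pair_idx) + 1L]] <- c(i, j)
    }
  }
  rej <- fdr_bh(pair_p, q)
  sig <- matrix(FALSE, k, k, dimnames = dimnames(rho))
  for (m in seq_along(pair_idx)) {
    ij <- pair_idx[[m]]
    sig[ij[1], ij[2]] <- sig[ij[2], ij[1]] <- rej[m]
  }
  list(rho = rho, p = pmat, significant = sig)
}

#' Shuffle-null parameter correlation matrix
#'
#' Guard against fitting-induced spurious correlations: each parameter
#' column of the ground-truth table is independently permuted across
#' subjects (destroying all covariation), sessions are re-simulated from the
#' shuffled parameters on the cohort's task sets, the model is refitted, and
#' the fitted parameters are correlated. With `refit = FALSE`, the shuffled
#' parameters are correlated directly (a fast shortcut whose null is exact).
#'
#' @param cohort An `nb_cohort`.
#' @param refit Re-simulate and refit (`TRUE`) or correlate shuffled truth
#'   directly.
#' @param permutations Optional list of per-column permutations (by column
#'   name of the 12-column matrix); random when `NULL`. Identity
#'   permutations reproduce the unshuffled matrix.
#' @param seed Base seed for the refitting stage.
#' @param ... Fitting settings passed to [fit_cohort()].
#' @return As [param_corr_matrix()], computed on the shuffled (or refitted)
#'   parameters.
#' @export
shuffle_null_recovery <- function(cohort, refit = TRUE, permutations = NULL,
                                  seed = 1L, ...) {
  stopifnot(inherits(cohort, "nb_cohort"))
  pm <- param_matrix(cohort$truth)
  n <- nrow(pm)
  if (is.null(permutations)) {
    permutations <- lapply(seq_len(ncol(pm)), function(i) sample.int(n))
    names(permutations) <- colnames(pm)
  }
  shuffled <- pm
  for (cn in colnames(pm)) {
    shuffled[, cn] <- pm[permutations[[cn]], cn]
  }
  if (!refit) {
    return(param_corr_matrix(shuffled))
  }
  # rebuild a long truth table from the shuffled matrix, simulate, refit
  subjects <- sort(unique(cohort$truth$subject))
  sessions <- list()
  truth_rows <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    ts <- if (length(cohort$task_sets) >= si && !is.null(cohort$task_sets[[si]])) {
      cohort$task_sets[[si]]
    } else {
      cohort$task_sets[[1]]
    }
    for (cond in NB_CONDITIONS) {
      pars <- agent_params(
        alpha = shuffled[si, paste0("alpha_", cond)],
        zeta = shuffled[si, paste0("zeta_", cond)],
        delta = shuffled[si, paste0("delta_", cond)],
        tau = shuffled[si, paste0("tau_", cond)])
      ses <- run_session(pars, ts$blocks[ts$blocks$condition == cond, ])
      ses$subject <- s
      sessions[[length(sessions) + 1L]] <- ses
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(subject = s, condition = cond, alpha = pars$alpha,
                   zeta = pars$zeta, delta = pars$delta, tau = pars$tau)
    }
  }
  sessions <- do.call(rbind, sessions)
  fits <- fit_cohort(sessions, model = "full", seed = seed, ...)
  param_corr_matrix(param_matrix(fits))
}

#' Median-split comparison of a behavioral metric
#'
#' Splits subjects at the median of a parameter (with the median subject
#' assigned to the lower half) and compares the metric between halves with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param metric Numeric vector (one value per subject).
#' @param split_by Numeric vector used for the split.
#' @return A list with `difference` (mean upper minus mean lower), `p_value`,
#'   `n_lower`, `n_upper`.
#' @export
median_split_compare <- function(metric, split_by) {
  n <- length(metric)
  stopifnot(length(split_by) == n, n >= 4)
  if (length(unique(split_by)) == 1) {
    stop("median_split_compare: split variable is constant")
  }
  lower <- split_by <= median(split_by)
  wt <- suppressWarnings(wilcox.test(metric[!lower], metric[lower]))
  list(difference = mean(metric[!lower]) - mean(metric[lower]),
       p_value = wt$p.value, n_lower = sum(lower), n_upper = sum(!lower))
}

# Align bootstrap PCs to reference loadings by maximal absolute correlation,
# then flip signs to positive agreement; removes order/sign indeterminacy.
align_pcs <- function(ref_load, boot_load) {
  k <- ncol(ref_load)
  cors <- abs(cor(ref_load, boot_load))
  perm <- integer(k)
  used <- logical(k)
  for (i in seq_len(k)) {
    ord <- order(cors[i, ], decreasing = TRUE)
    pick <- ord[!used[ord]][1]
    perm[i] <- pick
    used[pick] <- TRUE
  }
  out <- boot_load[, perm, drop = FALSE]
  for (i in seq_len(k)) {
    if (cor(ref_load[, i], out[, i]) < 0) out[, i] <- -out[, i]
  }
  out
}

# Core PCA summaries for a standardized matrix: loadings, eigenvalues,
# percent variance explained (total and per condition), per-parameter R^2.
pca_core <- function(x) {
  x <- scale(x)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  lam <- pc$sdev^2
  k <- ncol(x)
  ve <- 100 * lam / sum(lam)
  # R^2 of each standardized column regressed on each PC score equals
  # loading^2 * eigenvalue for standardized data
  r2 <- sweep(pc$rotation^2, 2, lam, `*`)
  conds <- unique(sub("^.*_", "", colnames(x)))
  ve_cond <- sapply(conds, function(cond) {
    cols <- grepl(paste0("_", cond, "$"), colnames(x))
    100 * colMeans(r2[cols, , drop = FALSE])
  })
  list(loadings = pc$rotation, eigenvalues = lam, var_explained = ve,
       var_explained_condition = t(ve_cond), r2 = r2)
}

#' PCA of standardized model parameters with bootstrap and shuffle null
#'
#' Eigen-decomposition of the standardized subjects x 12 parameter matrix.
#' Reports per-PC percent variance explained (summing to 100 over all PCs),
#' per-condition variance explained (mean R^2 of the condition's four
#' columns on each PC score), and per-parameter R^2. Bootstrap CIs resample
#' subjects and re-align PCs to the full-sample solution (matching by
#' maximal absolute loading correlation, then sign-flipping); the shuffle
#' null permutes every column independently before each decomposition.
#'
#' @param pm Subjects x parameters matrix from [param_matrix()] (>= 20
#'   subjects).
#' @param n_boot Bootstrap and shuffle resamples (default 1000).
#' @return An `nb_pca` list: `loadings`, `var_explained`,
#'   `var_explained_condition`, `r2`, `boot_ci` (2.5/97.5% quantiles of
#'   variance explained), `shuffle_var_explained` (null mean per PC),
#'   `p_vs_null` (one-sided bootstrap-vs-shuffle comparison per PC).
#' @export
pca_params <- function(pm, n_boot = 1000) {
  stopifnot(nrow(pm) >= 20)
  full <- pca_core(pm)
  k <- ncol(pm); n <- nrow(pm)
  boot_ve <- matrix(NA_real_, n_boot, k)
  shuf_ve <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bx <- pm[idx, , drop = FALSE]
    if (any(apply(bx, 2, sd) == 0)) next
    bpc <- pca_core(bx)
    # order eigenvalues by alignment with the full-sample loadings
    al <- align_pcs(full$loadings, bpc$loadings)
    ord <- match(colnames(al), colnames(bpc$loadings))
    boot_ve[b, ] <- bpc$var_explained[ord]
    sx <- apply(pm, 2, function(col) col[sample.int(n)])
    shuf_ve[b, ] <- pca_core(sx)$var_explained
  }
  boot_ci <- apply(boot_ve, 2, quantile, probs = c(0.025, 0.975),
                   na.rm = TRUE)
  p_vs_null <- vapply(seq_len(k), function(j) {
    ok <- !is.na(boot_ve[, j])
    mean(boot_ve[ok, j] <= shuf_ve[ok, j])
  }, numeric(1))
  structure(list(loadings = full$loadings,
                 var_explained = full$var_explained,
                 var_explained_condition = full$var_explained_condition,
                 r2 = full$r2, boot_ci = boot_ci,
                 shuffle_var_explained = colMeans(shuf_ve, na.rm = TRUE),
                 p_vs_null = p_vs_null, n_boot = n_boot),
            class = "nb_pca")
}

#' Analytic power to detect a correlation (Fisher z)
#'
#' Two-sided power of the test of zero correlation at sample size `n` using
#' the Fisher z approximation: `power = Phi(atanh(rho) sqrt(n - 3) -
#' z_{1-alpha/2})` plus the (negligible) opposite tail.
#'
#' @param rho True correlation.
#' @param n Sample size.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
power_corr_fisher <- function(rho, n, alpha = 0.05) {
  stopifnot(n > 3, abs(rho) < 1)
  zr <- atanh(rho) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / 2)
  pnorm(zr - zc) + pnorm(-zr - zc)
}
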