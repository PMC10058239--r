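# The statistical layer: correlations, FDR, median splits, PCA, power.

test_that("spearman correlation matches hand-computed rank arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # d = (0-(-1)) ... rank differences (0,1,-1,1,0) -> rho = 1 - 6*4/120
  expect_equal(spearman_cor(x, y)$rho, 0.8)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), y), "constant")
})

test_that("partial spearman removes shared dependence on the control", {
  set.seed(61)
  n <- 400
  z <- rnorm(n)
  # independent control: partial matches plain spearman within noise
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  ps <- partial_spearman(x, y, z)
  expect_equal(ps$rho, spearman_cor(x, y)$rho, tolerance = 0.08)
  # x = z: self-removal
  expect_lt(abs(partial_spearman(z, y, z)$rho), 0.12)
  # y = x + z retains a positive partial association with x
  y2 <- x + z
  expect_gt(partial_spearman(x, y2, z)$rho, 0.5)
  expect_lt(partial_spearman(x, y2, z)$p_value, 1e-6)
})

test_that("Benjamini-Hochberg flags match the step-up thresholds", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.5)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 6)), rep(FALSE, 6))
  expect_equal(fdr_bh(0.01), TRUE)
})

test_that("parameter correlation matrices are symmetric with FDR-controlled flags", {
  set.seed(62)
  fits <- expand.grid(subject = 1:40, condition = c("Ref", "S+", "V+"),
                      stringsAsFactors = FALSE)
  fits$alpha <- runif(nrow(fits))
  fits$zeta <- rlnorm(nrow(fits), -1, 0.4)
  fits$delta <- runif(nrow(fits))
  fits$tau <- rlnorm(nrow(fits), -2.5, 0.4)
  pm <- param_matrix(fits)
  expect_equal(dim(pm), c(40, 12))
  out <- param_corr_matrix(pm)
  expect_equal(out$rho, t(out$rho))
  expect_equal(diag(out$rho), rep(1, 12), ignore_attr = TRUE)
  # independent columns: false-positive rate controlled near the nominal level
  expect_lte(sum(out$significant) / 2, 4)
  # identical columns correlate perfectly
  pm2 <- pm
  pm2[, 2] <- pm2[, 1]
  expect_equal(param_corr_matrix(pm2)$rho[1, 2], 1)
})

test_that("standardized parameter matrices have unit-variance columns", {
  set.seed(63)
  fits <- expand.grid(subject = 1:25, condition = c("Ref", "S+", "V+"),
                      stringsAsFactors = FALSE)
  for (p in c("alpha", "zeta", "delta", "tau")) fits[[p]] <- runif(nrow(fits))
  pm <- param_matrix(fits, standardize = TRUE)
  expect_equal(colMeans(pm), rep(0, 12), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(pm, 2, var), rep(1, 12), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("median splits assign the median subject to the lower half", {
  metric <- c(1, 2, 3, 4, 10)
  split_var <- c(5, 4, 3, 2, 1)
  out <- median_split_compare(metric, split_var)
  # median split value 3 -> lower half = subjects with split_var <= 3
  expect_equal(out$n_lower, 3)
  expect_equal(out$n_upper, 2)
  expect_equal(out$difference, mean(c(1, 2)) - mean(c(3, 4, 10)))
  # metric equal across halves: no evidence of separation
  same <- median_split_compare(rep(c(1, 2), 5), rep(1:10))
  expect_gt(same$p_value, 0.5)
  expect_error(median_split_compare(1:4, rep(2, 4)), "constant")
})

test_that("maximal separation when the metric is the split variable", {
  v <- c(3, 9, 1, 7, 5, 8, 2, 6, 4, 10)
  out <- median_split_compare(v, v)
  # rank-sum of a perfect separation at n = 5 + 5: W = 25, p = 2/choose(10,5)*...
  expect_equal(out$p_value,
               suppressWarnings(wilcox.test(6:10, 1:5))$p.value)
  expect_equal(out$difference, 8 - 3)
})

test_that("PCA separates a correlated block and sums variance to 100%", {
  set.seed(64)
  n <- 300
  base <- matrix(rnorm(n * 12), n, 12)
  cols <- as.vector(outer(c("alpha", "zeta", "delta", "tau"),
                          c("Ref", "S+", "V+"), paste, sep = "_"))
  colnames(base) <- cols
  # two perfectly correlated columns, the rest independent
  base[, 2] <- base[, 1]
  out <- pca_params(base, n_boot = 60)
  expect_equal(sum(out$var_explained), 100, tolerance = 1e-9)
  # PC1 captures exactly the shared variance of the duplicated pair:
  # eigenvalue 2 of 12 -> 16.67%, loadings concentrated on those columns
  expect_equal(out$var_explained[1], 100 * 2 / 12, tolerance = 1)
  l1 <- out$loadings[, 1]
  expect_gt(sum(l1[1:2]^2), 0.8)
  # orthogonality of the PCs
  g <- crossprod(out$loadings)
  expect_equal(g, diag(12), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("shuffle null concentrates variance explained near isotropy", {
  set.seed(65)
  n <- 50
  x <- matrix(rnorm(n * 12), n, 12)
  colnames(x) <- as.vector(outer(c("alpha", "zeta", "delta", "tau"),
                                 c("Ref", "S+", "V+"), paste, sep = "_"))
  out <- pca_params(x, n_boot = 60)
  # independent data: shuffled and observed spectra agree; PC1 share near
  # the isotropic 100/12 with upward sampling bias
  expect_equal(out$shuffle_var_explained[1], out$var_explained[1],
               tolerance = 0.15 * out$var_explained[1])
  expect_gt(min(out$p_vs_null), 0.05)
  # bootstrap CIs cover the point estimates
  expect_true(all(out$boot_ci[1, ] <= out$var_explained + 1e-9))
  expect_true(all(out$boot_ci[2, ] >= out$var_explained - 1e-9))
})

test_that("cohorts with latent parameter dependencies yield interpretable PCs", {
  set.seed(66)
  pop <- population_spec("default")
  truth <- draw_cohort_params(80, pop)
  pm <- param_matrix(truth, standardize = TRUE)
  out <- pca_params(pm, n_boot = 40)
  # one of the leading PCs is dominated by choice temperature, another by
  # learning noise (loadings aggregated within parameter across conditions)
  share <- function(pc, param) {
    sum(out$loadings[grepl(paste0("^", param, "_"), rownames(out$loadings)),
                     pc]^2)
  }
  lead <- 1:3
  tau_pc <- lead[which.max(vapply(lead, share, numeric(1), param = "tau"))]
  zeta_pc <- lead[which.max(vapply(lead, share, numeric(1), param = "zeta"))]
  expect_true(tau_pc != zeta_pc)
  expect_gt(share(tau_pc, "tau"), 0.25)
  expect_gt(share(zeta_pc, "zeta"), 0.25)
})

test_that("the no-refit shuffle null destroys parameter correlations", {
  set.seed(67)
  pop <- population_spec("default")
  cohort <- list(truth = draw_cohort_params(60, pop))
  class(cohort) <- "nb_cohort"
  out <- shuffle_null_recovery(cohort, refit = FALSE)
  off <- out$rho[upper.tri(out$rho)]
  expect_lt(max(abs(off)), 0.45)
  expect_lte(sum(out$significant) / 2, 4)
  # identity permutations reproduce the unshuffled matrix
  pm <- param_matrix(cohort$truth)
  idperm <- setNames(rep(list(seq_len(nrow(pm))), 12), colnames(pm))
  out_id <- shuffle_null_recovery(cohort, refit = FALSE,
                                  permutations = idperm)
  expect_equal(out_id$rho, param_corr_matrix(pm)$rho)
})

test_that("analytic Fisher-z power matches a direct simulation", {
  p <- power_corr_fisher(0.2, 200)
  expect_equal(p, 0.812, tolerance = 0.01)
  # simulation oracle at modest replication count
  set.seed(68)
  hits <- mean(replicate(600, {
    x <- rnorm(100)
    y <- 0.3 * x + rnorm(100) * sqrt(1 - 0.09)
    cor.test(x, y)$p.value < 0.05
  }))
  expect_equal(power_corr_fisher(0.3, 100), hits, tolerance = 0.08)
})

test_that("rank-sum and signed-rank wrappers agree with a permutation oracle", {
  set.seed(69)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.8, 1.1, 2.0, 1.5)
  w <- suppressWarnings(wilcox.test(x, y))
  # exhaustive permutation distribution of the rank-sum statistic
  all_r <- rank(c(x, y))
  combs <- combn(9, 5)
  stat_obs <- sum(all_r[1:5]) - 5 * 6 / 2
  stats <- apply(combs, 2, function(ix) sum(all_r[ix]) - 15)
  p_perm <- mean(abs(stats - 10) >= abs(stat_obs - 10))
  expect_equal(w$p.value, p_perm, tolerance = 0.02)
})
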