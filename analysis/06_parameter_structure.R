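#!/usr/bin/env Rscript
# Covariation structure of fitted parameters across the synthetic cohort:
# the 12 x 12 rank-correlation matrix with FDR flags, its shuffle null,
# the partial correlation of learning noise and choice temperature given
# learning rate, and PCA with bootstrap CIs and a shuffle null.

suppressPackageStartupMessages(library(noisybandit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

fits <- read_params_csv("results/fits.csv")
pm <- param_matrix(fits)

corr <- param_corr_matrix(pm)
write.csv(corr$rho, "results/param_corr.csv")
cat(sprintf("significant off-diagonal correlations after FDR: %d of 66\n",
            sum(corr$significant) / 2))

# key between-parameter correlations, pooled within condition
for (cond in c("Ref", "S+", "V+")) {
  sub <- fits[fits$condition == cond, ]
  za <- spearman_cor(sub$zeta, sub$alpha)
  ta <- spearman_cor(sub$tau, sub$alpha)
  cat(sprintf("%s: rho(zeta, alpha) = %.2f (p = %.3f); rho(tau, alpha) = %.2f (p = %.3f)\n",
              cond, za$rho, za$p_value, ta$rho, ta$p_value))
}
ps <- partial_spearman(fits$zeta, fits$tau, fits$alpha)
cat(sprintf("partial rho(zeta, tau | alpha) pooled: %.2f (p = %.3f)\n",
            ps$rho, ps$p_value))

# shuffle null without refitting (the full refit null is run at reduced
# scale below)
set.seed(seed + 500L)
truth <- read_params_csv("results/truth.csv")
cohort <- structure(list(truth = truth), class = "nb_cohort")
null_fast <- shuffle_null_recovery(cohort, refit = FALSE)
cat(sprintf("no-refit shuffle null: max |rho| = %.2f, significant cells: %d\n",
            max(abs(null_fast$rho[upper.tri(null_fast$rho)])),
            sum(null_fast$significant) / 2))
write.csv(null_fast$rho, "results/param_corr_shuffle_null.csv")

# PCA of standardized parameters (needs at least 20 retained subjects)
set.seed(seed + 600L)
if (nrow(pm) < 20) {
  cat("\nfewer than 20 retained subjects; skipping the PCA stage\n")
  quit(save = "no", status = 0)
}
pca <- pca_params(pm, n_boot = 1000)
cat("\npercent variance explained (first 4 PCs):",
    paste(sprintf("%.1f", pca$var_explained[1:4]), collapse = ", "), "\n")
cat("shuffle-null mean (first 4 PCs):",
    paste(sprintf("%.1f", pca$shuffle_var_explained[1:4]), collapse = ", "),
    "\n")
cat("one-sided bootstrap-vs-null p (first 4 PCs):",
    paste(sprintf("%.3f", pca$p_vs_null[1:4]), collapse = ", "), "\n")
jsonlite::write_json(
  list(var_explained = pca$var_explained,
       var_explained_condition = as.data.frame(pca$var_explained_condition),
       boot_ci = as.data.frame(t(pca$boot_ci)),
       shuffle_var_explained = pca$shuffle_var_explained,
       p_vs_null = pca$p_vs_null,
       loadings = as.data.frame(pca$loadings)),
  "results/pca.json", digits = NA)
cat("\nwrote results/{param_corr*.csv,pca.json}\n")
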