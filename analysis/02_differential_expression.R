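#!/usr/bin/env Rscript
# Stage 2: median-of-ratios normalization, pairwise per-timepoint DE versus
# baseline and impulse-model longitudinal DE within each outcome group, and
# their combination into per-group DEG sets. Also the baseline
# remission-vs-non-remission contrast (diagnosis-adjusted) and the PCA
# covariate scan of baseline samples.

suppressPackageStartupMessages(library(tnfomics))

expr <- read_counts("results/cohort/counts.tsv")
design <- read_design("results/cohort/design.tsv")
expr <- normalize_counts(expr)
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

groups <- c("remission", "non_remission")
deg_sets <- list()
for (grp in groups) {
  pw <- lapply(setdiff(timepoint_levels(), "baseline"), function(tp)
    pairwise_de(expr, design, grp, tp))
  lg <- longitudinal_de(expr, design, grp)
  deg_sets[[grp]] <- combine_deg_sets(pw, lg, fdr_threshold = 0.05)
  write.table(do.call(rbind, pw), sprintf("results/de/pairwise_%s.tsv", grp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(lg, sprintf("results/de/longitudinal_%s.tsv", grp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(deg_sets[[grp]]),
              sprintf("results/de/deg_set_%s.tsv", grp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d DEGs (pairwise and longitudinal combined), %d longitudinal-only.\n",
              grp, nrow(deg_sets[[grp]]),
              sum(deg_sets[[grp]]$longitudinal & !deg_sets[[grp]]$pairwise)))
}
parts <- partition_deg_sets(deg_sets$remission, deg_sets$non_remission)
cat(sprintf("Shared between groups: %d genes; remission-only: %d; non-remission-only: %d.\n",
            length(parts$shared), length(parts$remission_only),
            length(parts$non_remission_only)))

bl <- baseline_contrast(expr, design)
write.table(bl, "results/de/baseline_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Baseline contrast: %d genes nominally significant (p < 0.05) after diagnosis adjustment.\n",
            sum(bl$p_value < 0.05, na.rm = TRUE)))

base_ids <- design$sample_id[design$assay == "rna" & design$timepoint == "baseline"]
expr_base <- expression_matrix(expr$counts[, base_ids])
expr_base <- normalize_counts(expr_base)
scan <- pca_covariate_scan(expr_base, design, covariates = c("group", "diagnosis"))
write.table(scan$correlations, "results/de/pca_covariate_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("PCA scan: leading components checked against outcome and diagnosis",
    "(partial correlation controls diagnosis).\n")
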