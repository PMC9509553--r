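#!/usr/bin/env Rscript
# Stage 1: simulate the default longitudinal two-omics cohort (24 IBD
# patients starting anti-TNF therapy, 12 reaching remission at week 14) and
# write it in the pipeline's file dialects together with the ground-truth
# manifest.

suppressPackageStartupMessages(library(tnfomics))

seed <- 1L
cohort <- simulate_cohort(sim_config(), seed = seed)
write_cohort(cohort, "results/cohort")

cat(sprintf(
  "Simulated cohort (seed %d): %d genes x %d RNA samples, %d probes x %d methylation samples.\n",
  seed, nrow(cohort$expr$counts), ncol(cohort$expr$counts),
  nrow(cohort$meth$beta), ncol(cohort$meth$beta)))
cat(sprintf(
  "Planted: %d DE genes (%d remission-specific), %d modules (%d disrupted in remitters),\n  %d DMPs, %d cis pairs (%.0f%% negative), %d predictive genes.\n",
  nrow(cohort$truth$de_genes),
  sum(cohort$truth$de_genes$group_specificity == "remission"),
  length(unique(cohort$truth$module_membership)),
  nrow(cohort$truth$disrupted_modules),
  nrow(cohort$truth$planted_dmps), nrow(cohort$truth$cis_pairs),
  100 * mean(cohort$truth$cis_pairs$sign == -1),
  length(cohort$truth$predictive_features)))
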