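#!/usr/bin/env Rscript
# Stage 8: score every stage's outputs against the ground-truth manifest of
# the simulated cohort: DEG sensitivity / observed FDR, module ARI,
# disrupted-module recovery, DMP sensitivity, cis-pair sensitivity and sign
# recovery, and prediction AUC.

suppressPackageStartupMessages(library(tnfomics))

truth <- jsonlite::read_json("results/cohort/ground_truth.json",
                             simplifyVector = TRUE)
truth$module_membership <- unlist(truth$module_membership)
class(truth) <- "ground_truth"

mod_tab <- read.delim("results/network/modules.tsv")
ctr <- read.delim("results/preservation/contrast.tsv")
cis <- read.delim("results/integration/cis_pairs.tsv")
dmps <- list(
  remission_2w = read.delim("results/methylation/dmp_remission_2w.tsv"),
  remission_6w = read.delim("results/methylation/dmp_remission_6w.tsv"),
  non_remission_2w = read.delim("results/methylation/dmp_non_remission_2w.tsv"),
  non_remission_6w = read.delim("results/methylation/dmp_non_remission_6w.tsv"))
deg_sets <- list(
  remission = read.delim("results/de/deg_set_remission.tsv"),
  non_remission = read.delim("results/de/deg_set_non_remission.tsv"))
auc <- read.delim("results/prediction/auc_by_layer.tsv")

rec <- evaluate_recovery(truth, list(
  deg_sets = deg_sets,
  modules = structure(list(membership = setNames(mod_tab$module,
                                                 mod_tab$gene_id)),
                      class = "module_set"),
  preservation_contrast = ctr,
  dmps = dmps,
  cis_pairs = cis,
  prediction = list(auc = auc$auc[auc$layer == "dnam_deg"],
                    n_patients = 24)))

flat <- data.frame(
  metric = c("deg_sensitivity_remission", "deg_observed_fdr_remission",
             "module_ari", "disrupted_modules_exact",
             "dmp_sensitivity_remission_2w", "dmp_sensitivity_non_remission_2w",
             "cis_sensitivity", "cis_observed_fdr", "cis_frac_negative",
             "cis_sign_accuracy", "prediction_auc_dnam_deg"),
  value = c(rec$de$remission$sensitivity, rec$de$remission$observed_fdr,
            rec$modules$ari, as.numeric(rec$disruption$exact_match),
            rec$dmp$remission_2w$sensitivity,
            rec$dmp$non_remission_2w$sensitivity,
            rec$cis$sensitivity, rec$cis$observed_fdr, rec$cis$frac_negative,
            rec$cis$sign_accuracy, auc$auc[auc$layer == "dnam_deg"]))
write.table(flat, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Recovery summary (results/recovery.tsv):\n")
print(flat, row.names = FALSE)
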