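#!/usr/bin/env Rscript
# Stage 7: random-forest prediction of week-14 remission from baseline +
# week-2 features: DNAm-linked DEG expression (the integration layer), DEG
# expression, DMP betas, and the clinical covariates, each with in-fold
# shadow-importance feature selection and 10-fold cross-validated AUC.

suppressPackageStartupMessages(library(tnfomics))

expr <- normalize_counts(read_counts("results/cohort/counts.tsv"))
meth <- filter_probes(read_betas("results/cohort/betas.tsv",
                                 "results/cohort/probe_annotation.tsv"))
design <- read_design("results/cohort/design.tsv")
dir.create("results/prediction", showWarnings = FALSE, recursive = TRUE)

cis <- read.delim("results/integration/cis_pairs.tsv")
linked <- unique(cis$gene_id[cis$significant %in% TRUE])
degs <- read.delim("results/de/deg_set_remission.tsv")$gene_id
dmps <- with(read.delim("results/methylation/dmp_remission_2w.tsv"),
             probe_id[significant])

layers <- list(
  dnam_deg = assemble_features(design, expr = expr, genes = linked),
  deg = assemble_features(design, expr = expr, genes = degs),
  dmp = assemble_features(design, meth = meth, probes = dmps),
  clinical = assemble_features(design, clinical = TRUE))

summary <- do.call(rbind, lapply(names(layers), function(nm) {
  pr <- cv_auc(layers[[nm]], k_folds = 10, seed = 701)
  write.table(pr$roc, sprintf("results/prediction/roc_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("Layer %-8s: %3d features in, 10-fold CV AUC = %.3f\n",
              nm, ncol(layers[[nm]]$x), pr$auc))
  data.frame(layer = nm, n_features = ncol(layers[[nm]]$x), auc = pr$auc)
}))
write.table(summary, "results/prediction/auc_by_layer.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# external-application style confusion report: hold out a third of patients,
# train on the rest with the DNAm-DEG layer
fm <- layers$dnam_deg
set.seed(702)
hold <- sort(sample(nrow(fm$x), round(nrow(fm$x) / 3)))
fit <- ranger::ranger(x = as.data.frame(fm$x[-hold, ]), y = fm$labels[-hold],
                      num.trees = 500, probability = TRUE, seed = 703,
                      num.threads = 1)
prob <- predict(fit, data = as.data.frame(fm$x[hold, ]))$predictions[, "remission"]
pred <- ifelse(prob >= 0.5, "remission", "non_remission")
conf <- confusion_report(pred, as.character(fm$labels[hold]),
                         n_bootstrap = 100, seed = 704)
write.table(conf, "results/prediction/holdout_confusion.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Hold-out confusion (n = %d): accuracy %.2f (95%% CI %.2f-%.2f).\n",
            length(hold), conf$value[conf$statistic == "accuracy"],
            attr(conf, "accuracy_ci")[1], attr(conf, "accuracy_ci")[2]))
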