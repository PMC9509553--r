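pred_fixture <- function(n_pat = 20, n_genes = 12, informative = 0, shift = 3,
                         seed = 17) {
  withr::with_seed(seed, {
    design <- tiny_design(n_pat)
    rd <- design[design$assay == "rna", ]
    mu <- matrix(100, n_genes, nrow(rd))
    if (informative > 0)
      mu[seq_len(informative), rd$group == "remission"] <- 100 * exp(shift)
    counts <- named_counts(matrix(rnbinom(length(mu), mu = mu, size = 20),
                                  n_genes, nrow(rd)), samples = rd$sample_id)
    list(expr = normalize_counts(expression_matrix(counts)), design = design)
  })
}

test_that("feature assembly tags provenance and blocks late timepoints", {
  fx <- pred_fixture(n_pat = 6)
  fm <- assemble_features(fx$design, expr = fx$expr, genes = c("g01", "g02"))
  expect_equal(ncol(fm$x), 4)                       # 2 genes x {baseline, 2w}
  expect_setequal(unique(fm$provenance$timepoint), c("baseline", "2w"))
  expect_equal(nrow(fm$x), 6)
  expect_error(assemble_features(fx$design, expr = fx$expr, genes = "g01",
                                 timepoints = c("baseline", "6w")), "baseline and 2w")
})

test_that("clinical features are exactly the four covariates at two timepoints", {
  fx <- pred_fixture(n_pat = 6)
  d <- fx$design
  d$CRP <- 5; d$IL6 <- 2; d$tryptophan <- 60; d$activity_score <- 4
  fm <- assemble_features(d, clinical = TRUE)
  expect_equal(ncol(fm$x), 8)
  expect_setequal(unique(fm$provenance$id),
                  c("CRP", "IL6", "tryptophan", "activity_score"))
})

test_that("patients with incomplete features are dropped with a warning", {
  fx <- pred_fixture(n_pat = 6)
  e <- fx$expr
  e$normalized["g01", fx$design$sample_id[fx$design$patient_id == "P03" &
                                            fx$design$timepoint == "2w" &
                                            fx$design$assay == "rna"]] <- NA
  expect_warning(fm <- assemble_features(fx$design, expr = e, genes = "g01"),
                 "P03")
  expect_equal(nrow(fm$x), 5)
})

test_that("shadow-importance selection keeps real signals and rejects noise", {
  fx <- pred_fixture(informative = 1, shift = 3, seed = 23)
  fm <- assemble_features(fx$design, expr = fx$expr,
                          genes = sprintf("g%02d", 1:12))
  sel <- select_features(fm, seed = 4)
  expect_true(any(grepl("\\|g01\\|", sel)))

  null_fx <- pred_fixture(informative = 0, seed = 29)
  fm0 <- assemble_features(null_fx$design, expr = null_fx$expr,
                           genes = sprintf("g%02d", 1:12))
  sel0 <- select_features(fm0, seed = 4)
  expect_lte(length(sel0), 0.15 * ncol(fm0$x))

  # a duplicated informative column still surfaces
  fm_dup <- fm
  fm_dup$x <- cbind(fm$x, dup = fm$x[, grep("\\|g01\\|baseline", colnames(fm$x))])
  colnames(fm_dup$x)[ncol(fm_dup$x)] <- "expression|g01dup|baseline"
  sel_dup <- select_features(fm_dup, seed = 4)
  expect_true(any(grepl("g01", sel_dup)))

  one_class <- fm
  one_class$labels <- factor(rep("remission", nrow(fm$x)),
                             levels = c("non_remission", "remission"))
  expect_error(select_features(one_class), "both classes")
})

test_that("cross-validated AUC separates planted classes and is fold-deterministic", {
  fx <- pred_fixture(informative = 3, shift = 3, seed = 37)
  fm <- assemble_features(fx$design, expr = fx$expr,
                          genes = sprintf("g%02d", 1:12))
  rep1 <- cv_auc(fm, k_folds = 10, seed = 11)
  expect_gte(rep1$auc, 0.95)
  expect_equal(rep1$k_folds, 10)
  rep2 <- cv_auc(fm, k_folds = 10, seed = 11)
  expect_identical(rep1$fold, rep2$fold)
  expect_identical(rep1$oof_probs, rep2$oof_probs)
  pm <- cv_auc(fm, k_folds = 10, seed = 11, paper_mode = TRUE)
  expect_gte(pm$auc, 0.95)
})

test_that("AUC is invariant under strictly monotone transforms of scores", {
  labels <- factor(rep(c("non_remission", "remission"), each = 10))
  scores <- withr::with_seed(3, runif(20))
  a1 <- roc_auc(scores, labels)$auc
  a2 <- roc_auc(qlogis(scores * 0.98 + 0.01), labels)$auc
  expect_equal(a1, a2)
  expect_gte(a1, 0); expect_lte(a1, 1)
})

test_that("the confusion report reproduces the validation-cohort worked example", {
  # n = 20, accuracy 0.85, sensitivity 1.00, specificity 0.50 force the
  # confusion matrix TP=14, FN=0, TN=3, FP=3
  predicted <- c(rep("remission", 17), rep("non_remission", 3))
  truth <- c(rep("remission", 14), rep("non_remission", 6))
  rep <- confusion_report(predicted, truth, n_bootstrap = 100, seed = 1)
  val <- setNames(rep$value, rep$statistic)
  expect_equal(unname(val["accuracy"]), 0.85)
  expect_equal(unname(val["sensitivity"]), 1.00)
  expect_equal(unname(val["specificity"]), 0.50)
  expect_equal(unname(round(val["ppv"], 2)), 0.82)
  expect_equal(unname(val["npv"]), 1.00)
  ci <- attr(rep, "accuracy_ci")
  expect_equal(round(ci, 2), c(0.62, 0.97))
})

test_that("confusion edge cases: perfection, zero denominators, empty input", {
  perfect <- confusion_report(c("a", "b", "a"), c("a", "b", "a"), seed = 1)
  expect_true(all(perfect$value == 1))
  expect_true(all(perfect$se == 0))
  one_sided <- confusion_report(rep("b", 4), c("a", "b", "a", "b"), seed = 1)
  expect_true(is.na(one_sided$value[one_sided$statistic == "npv"]) ||
                is.na(one_sided$value[one_sided$statistic == "ppv"]))
  expect_error(confusion_report(character(0), character(0)), "non-empty")
})

test_that("the exact binomial CI matches the brute-force Clopper-Pearson oracle", {
  rep <- confusion_report(c(rep("x", 17), rep("y", 3)),
                          c(rep("x", 17), rep("x", 3)), seed = 1)
  ci <- attr(rep, "accuracy_ci")
  oracle <- clopper_pearson_oracle(17, 20)
  expect_equal(ci, oracle, tolerance = 1e-4)
})
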