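# Outcome prediction: per-patient feature assembly, random-forest feature
# selection against label-permuted shadow importances, stratified
# cross-validated AUC, and confusion statistics with bootstrap standard
# errors.

#' Assemble a per-patient feature matrix
#'
#' Builds one row per patient from early-timepoint measurements (baseline and
#' week 2 only, so no information later than week 2 can leak into prediction).
#' Layers: `expr` contributes normalized expression of `genes` (e.g. DEGs or
#' DNAm-linked DEGs), `meth` beta values of `probes` (DMPs), `eigengenes`
#' module eigengene values, and `clinical` the design covariates CRP, IL6,
#' tryptophan and activity score. Each requested timepoint contributes its own
#' columns, tagged `layer|id|timepoint`. Patients missing any required sample
#' are dropped with a warning.
#'
#' @param design a [cohort_design()].
#' @param expr optional normalized [expression_matrix()].
#' @param genes gene ids for the expression layer.
#' @param meth optional [methylation_matrix()].
#' @param probes probe ids for the methylation layer.
#' @param eigengenes optional modules x samples matrix.
#' @param clinical logical; include the clinical covariate layer.
#' @param timepoints timepoints to use, subset of `c("baseline", "2w")`.
#' @return List of class `feature_matrix`: `x` (patients x features), `labels`
#'   (factor remission/non_remission), `provenance` (data.frame feature,
#'   layer, id, timepoint).
#' @export
assemble_features <- function(design, expr = NULL, genes = NULL,
                              meth = NULL, probes = NULL, eigengenes = NULL,
                              clinical = FALSE,
                              timepoints = c("baseline", "2w")) {
  bad_tp <- setdiff(timepoints, c("baseline", "2w"))
  if (length(bad_tp) > 0)
    stop_tnf("prediction features may only use baseline and 2w; got %s",
             paste(bad_tp, collapse = ", "))
  patients <- unique(design$patient_id)
  blocks <- list(); prov <- list()
  sample_of <- function(assay, tp) {
    d <- design_subset(design, assay = assay, timepoints = tp)
    stats::setNames(d$sample_id, d$patient_id)[patients]
  }
  add_block <- function(vals, layer, ids, tp) {
    colnames(vals) <- paste(layer, ids, tp, sep = "|")
    blocks[[length(blocks) + 1]] <<- vals
    prov[[length(prov) + 1]] <<- data.frame(
      feature = colnames(vals), layer = layer, id = ids, timepoint = tp,
      stringsAsFactors = FALSE)
  }
  for (tp in timepoints) {
    if (!is.null(expr) && length(genes) > 0) {
      smp <- sample_of("rna", tp)
      vals <- t(expr$normalized[genes, , drop = FALSE])[smp, , drop = FALSE]
      rownames(vals) <- patients
      add_block(vals, "expression", genes, tp)
    }
    if (!is.null(meth) && length(probes) > 0) {
      smp <- sample_of("methylation", tp)
      vals <- t(meth$beta[probes, , drop = FALSE])[smp, , drop = FALSE]
      rownames(vals) <- patients
      add_block(vals, "methylation", probes, tp)
    }
    if (!is.null(eigengenes)) {
      smp <- sample_of("rna", tp)
      vals <- t(eigengenes)[smp, , drop = FALSE]
      rownames(vals) <- patients
      add_block(vals, "module_eigengene", rownames(eigengenes), tp)
    }
    if (isTRUE(clinical)) {
      smp <- sample_of("rna", tp)
      cols <- intersect(c("CRP", "IL6", "tryptophan", "activity_score"),
                        names(design))
      if (length(cols) == 0)
        stop_tnf("no clinical covariate columns found in design")
      vals <- as.matrix(design[match(smp, design$sample_id), cols, drop = FALSE])
      rownames(vals) <- patients
      add_block(vals, "clinical", cols, tp)
    }
  }
  if (length(blocks) == 0) stop_tnf("no feature layer requested")
  x <- do.call(cbind, blocks)
  complete <- rowSums(is.na(x)) == 0
  if (!all(complete))
    warning(sprintf("dropping %d patient(s) with incomplete features: %s",
                    sum(!complete),
                    paste(patients[!complete], collapse = ", ")))
  x <- x[complete, , drop = FALSE]
  if (nrow(x) == 0) stop_tnf("no patient has complete feature data")
  labels <- design$group[match(rownames(x), design$patient_id)]
  structure(list(x = x,
                 labels = factor(labels, levels = c("non_remission", "remission")),
                 provenance = do.call(rbind, prov)),
            class = "feature_matrix")
}

ranger_importance <- function(x, y, seed, num_trees = 500) {
  fit <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = num_trees,
                        importance = "permutation", seed = seed,
                        num.threads = 1)
  fit$variable.importance
}

#' Select features by random-forest importance against shadow runs
#'
#' Computes permutation importances with a seeded random forest (500 trees)
#' and retains features whose importance exceeds the 95th percentile of the
#' pooled importances from `shadow_reps` label-permuted shadow forests.
#'
#' @param features a `feature_matrix` (or plain matrix with `labels`).
#' @param labels class labels (taken from `features` when a `feature_matrix`).
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @param shadow_reps label-permuted repetitions.
#' @param quantile percentile of the shadow importances used as threshold.
#' @return Character vector of selected feature names, with attributes
#'   `importance` and `threshold`.
#' @export
select_features <- function(features, labels = NULL, seed = 1,
                            num_trees = 500, shadow_reps = 10,
                            quantile = 0.95) {
  if (inherits(features, "feature_matrix")) {
    x <- features$x; y <- features$labels
  } else {
    x <- as.matrix(features); y <- factor(labels)
  }
  if (nlevels(droplevels(y)) < 2)
    stop_tnf("feature selection needs both classes present")
  if (min(table(droplevels(y))) < 2)
    stop_tnf("feature selection needs >= 2 patients per class")
  imp <- ranger_importance(x, y, seed = child_seed(seed, "rf"),
                           num_trees = num_trees)
  shadow <- with_seed(child_seed(seed, "shadow"), {
    unlist(lapply(seq_len(shadow_reps), function(i) {
      yp <- sample(y)
      ranger_importance(x, yp, seed = child_seed(seed, paste0("shadow", i)),
                        num_trees = num_trees)
    }))
  })
  thr <- stats::quantile(shadow, quantile, names = FALSE)
  sel <- names(imp)[imp > thr]
  structure(sel, importance = imp, threshold = thr)
}

# Deterministic stratified fold assignment: classes are shuffled internally,
# concatenated, and dealt cyclically so every fold is non-empty even when a
# class has fewer members than folds.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    ord <- unlist(lapply(levels(y), function(lev) sample(which(y == lev))))
    fold <- integer(length(y))
    fold[ord] <- rep_len(seq_len(k), length(ord))
    fold
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' @param scores numeric predicted probabilities of the positive class.
#' @param labels factor; the second level is the positive class.
#' @return List with `roc` (data.frame fpr, tpr, threshold) and `auc`
#'   (trapezoidal rule).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == levels(labels)[2]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Cross-validated AUC with in-fold feature selection
#'
#' Stratified k-fold cross-validation of a seeded random-forest classifier.
#' By default feature selection runs inside every training fold (no
#' selection leakage); `paper_mode = TRUE` reproduces single-step selection on
#' the full data before cross-validation. If a fold's training split lacks a
#' class the folds are redrawn with a shifted seed (up to 10 attempts).
#'
#' @param features a `feature_matrix`.
#' @param k_folds number of folds (default 10).
#' @param seed integer seed governing folds, selection and forests.
#' @param select run feature selection (in-fold unless `paper_mode`).
#' @param paper_mode select once on the full data before CV.
#' @param num_trees trees per forest.
#' @return List of class `prediction_report`: `auc`, `roc`, `oof_probs`,
#'   `fold`, `selected` (list per fold, or vector in paper mode),
#'   `n_patients`.
#' @export
cv_auc <- function(features, k_folds = 10, seed = 1, select = TRUE,
                   paper_mode = FALSE, num_trees = 500) {
  x <- features$x; y <- droplevels(features$labels)
  if (k_folds < 2) stop_tnf("k_folds must be >= 2")
  if (nlevels(y) < 2) stop_tnf("cross-validation needs both classes")
  k <- min(k_folds, min(table(y)) * 2, nrow(x))
  fold <- NULL
  for (attempt in 0:9) {
    f <- stratified_folds(y, k, child_seed(seed, paste0("folds", attempt)))
    ok <- all(vapply(seq_len(k), function(i)
      nlevels(droplevels(y[f != i])) == 2, logical(1)))
    if (ok) { fold <- f; break }
  }
  if (is.null(fold)) stop_tnf("could not build folds with both classes in training")
  pre_selected <- NULL
  if (select && paper_mode) {
    pre_selected <- select_features(features, seed = seed)
    if (length(pre_selected) == 0) pre_selected <- colnames(x)
  }
  oof <- rep(NA_real_, nrow(x))
  selected <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- fold != i; te <- fold == i
    if (!any(te)) next
    feats <- colnames(x)
    if (select && !paper_mode) {
      sel <- tryCatch(
        select_features(structure(list(x = x[tr, , drop = FALSE],
                                       labels = y[tr]),
                                  class = "feature_matrix"),
                        seed = child_seed(seed, paste0("sel", i))),
        error = function(e) character(0))
      if (length(sel) > 0) feats <- sel
    } else if (!is.null(pre_selected)) {
      feats <- pre_selected
    }
    selected[[i]] <- feats
    fit <- ranger::ranger(x = as.data.frame(x[tr, feats, drop = FALSE]),
                          y = y[tr], num.trees = num_trees,
                          probability = TRUE,
                          seed = child_seed(seed, paste0("fit", i)),
                          num.threads = 1)
    pr <- stats::predict(fit,
                         data = as.data.frame(x[te, feats, drop = FALSE]))
    oof[te] <- pr$predictions[, levels(y)[2]]
  }
  ra <- roc_auc(oof, y)
  structure(list(auc = ra$auc, roc = ra$roc, oof_probs = oof, fold = fold,
                 labels = y, selected = if (paper_mode) pre_selected else selected,
                 n_patients = nrow(x), k_folds = k, seed = seed),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: %d patients, %d-fold CV, AUC = %.3f\n",
              x$n_patients, x$k_folds, x$auc))
  invisible(x)
}

#' Confusion statistics with bootstrap standard errors
#'
#' Accuracy, sensitivity, specificity, PPV and NPV from the 2x2 confusion
#' matrix of predicted versus true labels (the second factor level is the
#' positive class), with bootstrap standard errors over patients and an exact
#' (Clopper-Pearson) binomial 95% confidence interval for accuracy.
#' Statistics with a zero denominator are reported missing.
#'
#' @param predicted,truth equal-length label vectors (coerced to a common
#'   factor).
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed integer seed for the bootstrap.
#' @return data.frame: statistic, value, se; attributes `confusion` (matrix)
#'   and `accuracy_ci` (exact 95% CI).
#' @export
confusion_report <- function(predicted, truth, n_bootstrap = 100, seed = 1) {
  if (length(predicted) == 0 || length(predicted) != length(truth))
    stop_tnf("predicted and truth must be non-empty vectors of equal length")
  levs <- levels(factor(c(as.character(truth), as.character(predicted))))
  pr <- factor(as.character(predicted), levels = levs)
  tr <- factor(as.character(truth), levels = levs)
  pos <- levs[length(levs)]
  stats_of <- function(pr, tr) {
    tp <- sum(pr == pos & tr == pos); fn <- sum(pr != pos & tr == pos)
    tn <- sum(pr != pos & tr != pos); fp <- sum(pr == pos & tr != pos)
    div <- function(a, b) if (b == 0) NA_real_ else a / b
    c(accuracy = (tp + tn) / length(pr),
      sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
      ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
  }
  obs <- stats_of(pr, tr)
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample(length(pr), replace = TRUE)
      stats_of(pr[idx], tr[idx])
    }, numeric(5))
  })
  se <- apply(boot, 1, stats::sd, na.rm = TRUE)
  n_correct <- sum(pr == tr)
  ci <- stats::binom.test(n_correct, length(pr))$conf.int
  out <- data.frame(statistic = names(obs), value = unname(obs),
                    se = unname(se), stringsAsFactors = FALSE)
  attr(out, "confusion") <- table(predicted = pr, truth = tr)
  attr(out, "accuracy_ci") <- as.numeric(ci)
  out
}
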