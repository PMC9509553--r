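# Recovery scoring of pipeline outputs against planted ground truth.

#' Adjusted Rand index between two labelings
#'
#' @param a,b equal-length label vectors over the same items.
#' @return ARI in \[-1, 1\]; 1 for identical partitions up to renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_tnf("labelings differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

sens_fdr <- function(called, truth_set, universe) {
  called <- intersect(called, universe)
  truth_set <- intersect(truth_set, universe)
  tp <- length(intersect(called, truth_set))
  list(sensitivity = if (length(truth_set) > 0) tp / length(truth_set) else NA_real_,
       observed_fdr = if (length(called) > 0) 1 - tp / length(called) else 0,
       n_called = length(called), n_true = length(truth_set))
}

#' Score pipeline outputs against planted ground truth
#'
#' Reports, per analysis stage, recovery of the planted structure: DEG
#' sensitivity and observed FDR per group; adjusted Rand index of the detected
#' module partition (over the network's gene universe); whether exactly the
#' planted disrupted modules were flagged by the preservation contrast; DMP
#' sensitivity/FDR per contrast; cis-pair sensitivity, FDR, sign accuracy and
#' recovered negative fraction; and the cross-validated AUC on the planted
#' predictive features versus permuted labels.
#'
#' @param truth a `ground_truth` from [simulate_cohort()].
#' @param outputs named list of pipeline stage outputs (see
#'   [run_pipeline()]): any of `deg_sets`, `modules`, `preservation_contrast`,
#'   `dmps`, `cis_pairs`, `prediction`.
#' @return Nested list of recovery metrics.
#' @export
evaluate_recovery <- function(truth, outputs) {
  rep_out <- list()
  if (!is.null(outputs$deg_sets)) {
    rep_out$de <- lapply(names(outputs$deg_sets), function(grp) {
      set <- outputs$deg_sets[[grp]]
      called <- if (is.data.frame(set)) set$gene_id else set
      if (length(setdiff(called, truth$genes)) > 0)
        stop_tnf("gene universe mismatch between outputs and truth")
      sens_fdr(called, truth$deg_by_group[[grp]], truth$genes)
    })
    names(rep_out$de) <- names(outputs$deg_sets)
  }
  if (!is.null(outputs$modules)) {
    membership <- outputs$modules$membership
    genes <- names(membership)
    bad <- setdiff(genes, truth$genes)
    if (length(bad) > 0)
      stop_tnf("module genes outside the simulated universe: %s", bad[1])
    truth_lab <- truth$module_membership[genes]
    truth_lab[is.na(truth_lab)] <- "unassigned"
    rep_out$modules <- list(
      ari = adjusted_rand_index(membership, truth_lab),
      n_detected = length(setdiff(unique(membership), "unassigned")),
      n_planted = length(unique(truth$module_membership)))
    # map detected modules to planted ones by best overlap
    det <- setdiff(unique(membership), "unassigned")
    map <- vapply(det, function(m) {
      g <- genes[membership == m]
      tl <- truth_lab[g]
      names(sort(table(tl[tl != "unassigned"]), decreasing = TRUE))[1] %||% NA_character_
    }, character(1))
    rep_out$modules$label_map <- map
    if (!is.null(outputs$preservation_contrast)) {
      pc <- outputs$preservation_contrast
      flagged_detected <- unique(pc$module[pc$flagged])
      flagged_planted <- sort(unique(stats::na.omit(map[flagged_detected])))
      planted <- sort(truth$disrupted_modules$module)
      rep_out$disruption <- list(
        flagged_modules = flagged_planted,
        planted_modules = planted,
        exact_match = identical(flagged_planted, planted))
    }
  }
  if (!is.null(outputs$dmps)) {
    rep_out$dmp <- lapply(names(outputs$dmps), function(nm) {
      tab <- outputs$dmps[[nm]]
      if (length(setdiff(tab$probe_id, truth$probes)) > 0)
        stop_tnf("probe universe mismatch between outputs and truth")
      called <- tab$probe_id[tab$significant]
      grp <- if (grepl("non_remission", nm)) "non_remission" else "remission"
      truth_probes <- truth$planted_dmps$probe_id[truth$planted_dmps$group == grp]
      sens_fdr(called, truth_probes, tab$probe_id)
    })
    names(rep_out$dmp) <- names(outputs$dmps)
  }
  if (!is.null(outputs$cis_pairs)) {
    cp <- outputs$cis_pairs
    key <- paste(cp$probe_id, cp$gene_id)
    truth_key <- paste(truth$cis_pairs$probe_id, truth$cis_pairs$gene_id)
    sig <- cp[isTRUE_vec(cp$significant), , drop = FALSE]
    sig_key <- paste(sig$probe_id, sig$gene_id)
    covered_truth <- intersect(truth_key, key)
    tp_key <- intersect(sig_key, truth_key)
    sign_ok <- if (length(tp_key) > 0) {
      obs_sign <- sign(sig$rho[match(tp_key, sig_key)])
      tru_sign <- truth$cis_pairs$sign[match(tp_key, truth_key)]
      mean(obs_sign == tru_sign)
    } else NA_real_
    rep_out$cis <- list(
      sensitivity = if (length(covered_truth) > 0)
        length(tp_key) / length(covered_truth) else NA_real_,
      observed_fdr = if (nrow(sig) > 0)
        1 - length(tp_key) / nrow(sig) else 0,
      sign_accuracy = sign_ok,
      frac_negative = if (nrow(sig) > 0)
        mean(sig$sign_class == "canonical_negative") else NA_real_,
      n_candidates = nrow(cp), n_significant = nrow(sig))
  }
  if (!is.null(outputs$prediction)) {
    rep_out$prediction <- list(auc = outputs$prediction$auc,
                               n_patients = outputs$prediction$n_patients)
  }
  rep_out
}
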