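# Cis methylation-expression integration: window mapping around DEG
# transcription start sites, Spearman correlation, permutation FDR, sign
# classification, module over-representation and cross-cohort concordance.

#' Map candidate cis DMP-DEG pairs
#'
#' Pairs every DMP probe with every DEG whose transcription start site lies on
#' the same chromosome within `window_bp` (inclusive). The signed distance is
#' `pos - tss`, with the sign flipped for "-"-strand genes, so positive values
#' are downstream in gene orientation.
#'
#' @param dmp_probes data.frame with `probe_id`, `chrom`, `pos`.
#' @param deg_genes character vector of DEG gene ids.
#' @param annotation a [gene_annotation()].
#' @param window_bp half-width of the cis window (default 5000).
#' @return data.frame: probe_id, gene_id, signed_distance.
#' @export
map_cis_pairs <- function(dmp_probes, deg_genes, annotation, window_bp = 5000) {
  ann <- annotation[annotation$gene_id %in% deg_genes, , drop = FALSE]
  if (length(intersect(unique(dmp_probes$chrom), unique(ann$chrom))) == 0 &&
      nrow(ann) > 0 && nrow(dmp_probes) > 0)
    stop_tnf("no shared chromosome names between probes (%s...) and genes (%s...)",
             dmp_probes$chrom[1], ann$chrom[1])
  rows <- list()
  for (ch in intersect(unique(dmp_probes$chrom), unique(ann$chrom))) {
    p <- dmp_probes[dmp_probes$chrom == ch, , drop = FALSE]
    g <- ann[ann$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      delta <- p$pos - g$tss[i]
      hit <- abs(delta) <= window_bp
      if (!any(hit)) next
      sd_bp <- if (g$strand[i] == "+") delta[hit] else -delta[hit]
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = p$probe_id[hit], gene_id = g$gene_id[i],
        signed_distance = as.integer(sd_bp), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe_id = character(0), gene_id = character(0),
                      signed_distance = integer(0))
  rownames(out) <- NULL
  out
}

# Samples with both omics layers, matched by (patient, timepoint) over the
# methylation timepoints; optionally restricted to one group.
matched_samples <- function(design, group = NULL) {
  rna <- design_subset(design, assay = "rna", group = group,
                       timepoints = methylation_timepoints())
  met <- design_subset(design, assay = "methylation", group = group)
  key_r <- paste(rna$patient_id, rna$timepoint)
  key_m <- paste(met$patient_id, met$timepoint)
  shared <- intersect(key_r, key_m)
  data.frame(patient_id = rna$patient_id[match(shared, key_r)],
             timepoint = as.character(rna$timepoint[match(shared, key_r)]),
             rna_sample = rna$sample_id[match(shared, key_r)],
             meth_sample = met$sample_id[match(shared, key_m)],
             stringsAsFactors = FALSE)
}

#' Spearman correlation of expression and methylation over cis pairs
#'
#' Correlates each candidate pair's normalized gene expression with its probe's
#' beta values over samples matched by (patient, timepoint) across the two
#' layers (the shared methylation timepoints). Samples are pooled across
#' outcome groups unless `group` is given.
#'
#' @param expr a normalized [expression_matrix()].
#' @param meth a [methylation_matrix()].
#' @param pairs a [map_cis_pairs()] table.
#' @param design a [cohort_design()].
#' @param group optional group restriction.
#' @return The pairs table with `rho` and `n_samples` added; constant inputs
#'   yield `NA` with a warning.
#' @export
correlate_pairs <- function(expr, meth, pairs, design, group = NULL) {
  ms <- matched_samples(design, group)
  if (nrow(ms) < 4)
    stop_tnf("need >= 4 matched expression/methylation samples, have %d", nrow(ms))
  e <- expr$normalized[pairs$gene_id, ms$rna_sample, drop = FALSE]
  b <- meth$beta[pairs$probe_id, ms$meth_sample, drop = FALSE]
  rho <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- e[i, ]; y <- b[i, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok], method = "spearman")
  }, numeric(1))
  if (anyNA(rho))
    warning(sprintf("%d pair(s) with constant or insufficient data; rho set NA",
                    sum(is.na(rho))))
  pairs$rho <- rho
  pairs$n_samples <- nrow(ms)
  pairs
}

#' Permutation FDR for cis-pair correlations
#'
#' Builds a pooled null by shuffling the patient identity of the methylation
#' layer (keeping each sample's timepoint) `n_permutations` times and
#' recomputing all pair |rho|. The empirical p-value of a pair is
#' `(1 + #{null |rho| >= observed}) / (1 + pooled null size)`, never zero;
#' Benjamini-Hochberg across pairs gives the FDR, with significance at
#' `fdr_threshold`. Sign classes: `canonical_negative` (rho < 0) vs
#' `positive`.
#'
#' @param pairs a [correlate_pairs()] table.
#' @param expr,meth,design as in [correlate_pairs()].
#' @param n_permutations at least 100.
#' @param seed integer seed.
#' @param fdr_threshold significance level.
#' @param group optional group restriction (must match the observed rho call).
#' @return The pairs table with `empirical_p`, `fdr`, `significant`,
#'   `sign_class`.
#' @export
permutation_fdr <- function(pairs, expr, meth, design, n_permutations = 100,
                            seed = 1, fdr_threshold = 0.05, group = NULL) {
  if (n_permutations < 100)
    stop_tnf("n_permutations must be >= 100, got %d", n_permutations)
  ms <- matched_samples(design, group)
  patients <- unique(ms$patient_id)
  if (length(patients) < 5)
    stop_tnf("need >= 5 patients to permute, have %d", length(patients))
  keep <- !is.na(pairs$rho)
  # rank-transform once; a patient permutation only reindexes rows
  e <- expr$normalized[pairs$gene_id, ms$rna_sample, drop = FALSE]
  b <- meth$beta[pairs$probe_id, ms$meth_sample, drop = FALSE]
  rx <- t(apply(e, 1, rank))
  ry <- t(apply(b, 1, rank))
  std <- function(m) {
    m <- m - rowMeans(m)
    s <- sqrt(rowSums(m^2))
    m / ifelse(s == 0, 1, s)
  }
  sx <- std(rx)
  null_abs <- with_seed(seed, {
    unlist(lapply(seq_len(n_permutations), function(i) {
      perm <- sample(patients)
      names(perm) <- patients
      new_key <- paste(perm[ms$patient_id], ms$timepoint)
      idx <- match(new_key, paste(ms$patient_id, ms$timepoint))
      ok <- !is.na(idx)
      yb <- b[, idx[ok], drop = FALSE]
      ryp <- t(apply(yb, 1, rank))
      sy <- std(ryp)
      sxp <- std(rx[, ok, drop = FALSE])
      abs(rowSums(sxp * sy))[keep]
    }))
  })
  null_abs <- null_abs[!is.na(null_abs)]
  n_null <- length(null_abs)
  sorted_null <- sort(null_abs)
  emp_p <- rep(NA_real_, nrow(pairs))
  ge_count <- n_null - findInterval(abs(pairs$rho[keep]) - 1e-12, sorted_null)
  emp_p[keep] <- (1 + ge_count) / (1 + n_null)
  pairs$empirical_p <- emp_p
  pairs$fdr <- stats::p.adjust(emp_p, method = "BH")
  pairs$significant <- !is.na(pairs$fdr) & pairs$fdr < fdr_threshold
  pairs$sign_class <- ifelse(pairs$rho < 0, "canonical_negative", "positive")
  pairs
}

#' Summarize correlation signs among significant cis pairs
#'
#' @param pairs a [permutation_fdr()] table (significant subset is used).
#' @return List: `pairs` (counts/fractions over pairs) and `genes` (per-gene
#'   rollup, a gene counted once per sign it shows).
#' @export
classify_signs <- function(pairs) {
  sig <- pairs[isTRUE_vec(pairs$significant), , drop = FALSE]
  if (nrow(sig) == 0) stop_tnf("no significant cis pairs to classify")
  n_neg <- sum(sig$sign_class == "canonical_negative")
  gene_neg <- unique(sig$gene_id[sig$sign_class == "canonical_negative"])
  gene_pos <- unique(sig$gene_id[sig$sign_class == "positive"])
  list(
    pairs = data.frame(
      n_pairs = nrow(sig), n_negative = n_neg, n_positive = nrow(sig) - n_neg,
      frac_negative = n_neg / nrow(sig)),
    genes = data.frame(
      n_genes = length(unique(sig$gene_id)),
      n_genes_negative = length(gene_neg),
      n_genes_positive = length(gene_pos)))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Over-representation of DNAm-linked genes in co-expression modules
#'
#' @param linked_genes genes appearing in significant cis pairs.
#' @param modules a `module_set` (its gene universe defines the background).
#' @return data.frame: module, module_size, observed, expected, ratio,
#'   p_value (chi-square on the 2x2 table). Empty modules are skipped.
#' @export
module_overrepresentation <- function(linked_genes, modules) {
  membership <- modules$membership
  universe <- names(membership)
  linked <- intersect(linked_genes, universe)
  mods <- setdiff(sort(unique(membership)), "unassigned")
  rows <- list()
  for (m in mods) {
    mg <- names(membership)[membership == m]
    if (length(mg) == 0) { warning(sprintf("module %s is empty; skipped", m)); next }
    obs <- length(intersect(linked, mg))
    expd <- length(mg) * length(linked) / length(universe)
    tab <- matrix(c(obs, length(linked) - obs,
                    length(mg) - obs,
                    length(universe) - length(mg) - (length(linked) - obs)),
                  nrow = 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[m]] <- data.frame(module = m, module_size = length(mg),
                            observed = obs, expected = expd,
                            ratio = if (expd > 0) obs / expd else NA_real_,
                            p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-cohort replication concordance
#'
#' Compares two cohorts' differential-expression tables (Spearman correlation
#' of log2 fold changes over shared genes, per contrast) and their significant
#' cis-pair tables (shared cis-linked genes and the fraction with preserved
#' correlation sign).
#'
#' @param de_a,de_b DE tables with `gene_id`, `contrast`, `log2_fold_change`.
#' @param cis_a,cis_b optional significant cis-pair tables with `gene_id`,
#'   `probe_id`, `rho`.
#' @return List with `lfc` (data.frame per contrast: rho, n_shared) and
#'   `cis` (n_shared_pairs, n_sign_preserved, frac_sign_preserved) when cis
#'   tables are given.
#' @export
replication_concordance <- function(de_a, de_b, cis_a = NULL, cis_b = NULL) {
  rows <- list()
  for (ct in intersect(unique(de_a$contrast), unique(de_b$contrast))) {
    a <- de_a[de_a$contrast == ct, ]
    b <- de_b[de_b$contrast == ct, ]
    shared <- intersect(a$gene_id, b$gene_id)
    if (length(shared) == 0) next
    rho <- stats::cor(a$log2_fold_change[match(shared, a$gene_id)],
                      b$log2_fold_change[match(shared, b$gene_id)],
                      method = "spearman", use = "complete.obs")
    rows[[ct]] <- data.frame(contrast = ct, rho = rho, n_shared = length(shared))
  }
  if (length(rows) == 0) stop_tnf("cohorts share no contrasts or genes")
  out <- list(lfc = do.call(rbind, rows))
  rownames(out$lfc) <- NULL
  if (!is.null(cis_a) && !is.null(cis_b)) {
    key_a <- paste(cis_a$probe_id, cis_a$gene_id)
    key_b <- paste(cis_b$probe_id, cis_b$gene_id)
    shared <- intersect(key_a, key_b)
    same <- sign(cis_a$rho[match(shared, key_a)]) ==
      sign(cis_b$rho[match(shared, key_b)])
    out$cis <- data.frame(
      n_shared_pairs = length(shared),
      n_sign_preserved = sum(same),
      frac_sign_preserved = if (length(shared) > 0) mean(same) else NA_real_,
      n_shared_genes = length(intersect(cis_a$gene_id, cis_b$gene_id)))
  }
  out
}
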