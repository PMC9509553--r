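# Combination and comparison of DEG sets from the pairwise and longitudinal
# analyses, and the PCA covariate scan.

#' Combine pairwise and longitudinal DEG calls for one group
#'
#' Builds the group's DEG set with provenance flags: which pairwise contrasts
#' and/or the longitudinal analysis called each gene at the FDR threshold. The
#' default combination is the union of the two analyses (matching the combined
#' reporting of pairwise and longitudinal results); `mode = "intersection"`
#' requires a call in both.
#'
#' @param pairwise_list list of [pairwise_de()] tables (one per timepoint) for
#'   the group.
#' @param longitudinal a [longitudinal_de()] table for the group.
#' @param fdr_threshold significance threshold on adjusted p-values.
#' @param mode `"union"` or `"intersection"`.
#' @return data.frame of class `deg_set`: `gene_id`, logical `pairwise`,
#'   `longitudinal`, character `provenance`.
#' @export
combine_deg_sets <- function(pairwise_list, longitudinal,
                             fdr_threshold = 0.05,
                             mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(pairwise_list) > 0) {
    uni <- sort(unique(unlist(lapply(pairwise_list, `[[`, "gene_id"))))
    if (nrow(longitudinal) > 0 &&
        length(intersect(uni, longitudinal$gene_id)) == 0 &&
        length(uni) > 0)
      stop_tnf("pairwise and longitudinal results share no genes; universe mismatch")
  }
  pw_hits <- list()
  for (tab in pairwise_list) {
    sig <- tab$gene_id[!is.na(tab$fdr) & tab$fdr < fdr_threshold]
    for (g in sig) {
      lab <- sub("_vs_baseline.*", "", tab$contrast[1])
      pw_hits[[g]] <- c(pw_hits[[g]], lab)
    }
  }
  lg_hits <- longitudinal$gene_id[!is.na(longitudinal$fdr) &
                                    longitudinal$fdr < fdr_threshold]
  genes <- switch(mode,
                  union = sort(union(names(pw_hits), lg_hits)),
                  intersection = sort(intersect(names(pw_hits), lg_hits)))
  out <- data.frame(
    gene_id = genes,
    pairwise = genes %in% names(pw_hits),
    longitudinal = genes %in% lg_hits,
    provenance = vapply(genes, function(g) {
      tags <- character(0)
      if (g %in% names(pw_hits))
        tags <- paste0("pairwise:", paste(sort(unique(pw_hits[[g]])), collapse = ","))
      if (g %in% lg_hits) tags <- c(tags, "longitudinal")
      paste(tags, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("deg_set", "data.frame")
  out
}

#' Partition two groups' DEG sets into group-only and shared genes
#'
#' @param set_remission,set_non_remission `deg_set` tables (or character
#'   vectors of gene ids).
#' @return List with `remission_only`, `non_remission_only`, `shared`; the
#'   three partitions are disjoint and cover the union.
#' @export
partition_deg_sets <- function(set_remission, set_non_remission) {
  g1 <- if (is.data.frame(set_remission)) set_remission$gene_id else set_remission
  g2 <- if (is.data.frame(set_non_remission)) set_non_remission$gene_id else set_non_remission
  list(remission_only = sort(setdiff(g1, g2)),
       non_remission_only = sort(setdiff(g2, g1)),
       shared = sort(intersect(g1, g2)))
}

#' Cross-tabulate two DEG collections by timepoint and direction
#'
#' Each input is a named list of gene-id vectors, the names of the form
#' `"<direction>@<timepoint>"` (e.g. `"up@4h"`). Returns the overlap count
#' matrix (rows = first collection's cells, columns = second's) plus a parallel
#' character matrix labeling cells `same-direction` / `opposite-direction`.
#'
#' @param set_a,set_b named lists of gene-id vectors.
#' @return List with integer matrix `counts` and character matrix `direction`.
#' @export
compare_deg_sets <- function(set_a, set_b) {
  dir_of <- function(nm) sub("@.*", "", nm)
  counts <- matrix(0L, length(set_a), length(set_b),
                   dimnames = list(names(set_a), names(set_b)))
  direction <- matrix(NA_character_, length(set_a), length(set_b),
                      dimnames = dimnames(counts))
  for (i in seq_along(set_a)) for (j in seq_along(set_b)) {
    counts[i, j] <- length(intersect(set_a[[i]], set_b[[j]]))
    direction[i, j] <- if (dir_of(names(set_a)[i]) == dir_of(names(set_b)[j]))
      "same-direction" else "opposite-direction"
  }
  list(counts = counts, direction = direction)
}

# First-order partial correlation from three pairwise correlations.
partial_cor <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' PCA of baseline expression with covariate and partial-correlation scan
#'
#' Principal components of log2(x + 1) gene-standardized normalized counts.
#' For each component, the Spearman correlation (rho, p) with each covariate is
#' reported, along with the first-order partial Spearman correlation between
#' the component and the outcome controlling for diagnosis (computed on
#' rank-transformed data).
#'
#' @param expr a normalized [expression_matrix()].
#' @param design a [cohort_design()] covering `expr`'s samples.
#' @param covariates design columns to correlate with (factors are rank-coded).
#' @param n_components number of leading components to report.
#' @return List with `scores` (samples x components), `explained` (variance
#'   fractions) and `correlations` (long data.frame: component, covariate, rho,
#'   p_value, partial_rho_outcome_given_diagnosis).
#' @export
pca_covariate_scan <- function(expr, design, covariates = c("group", "diagnosis"),
                               n_components = 5) {
  d <- design[match(colnames(expr$counts), design$sample_id), , drop = FALSE]
  if (nrow(d) < 3) stop_tnf("PCA scan needs at least 3 samples")
  x <- t(log_normalized(expr))                 # samples x genes
  keep <- apply(x, 2, stats::sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]

  num_cov <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  out_rank <- rank(num_cov(d$group))
  dia_rank <- rank(num_cov(d$diagnosis))
  rows <- list()
  for (j in seq_len(k)) for (cv in covariates) {
    v <- num_cov(d[[cv]])
    if (length(unique(v[!is.na(v)])) < 2) {
      warning(sprintf("covariate '%s' is constant; correlation undefined", cv))
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(scores[, j], v, method = "spearman",
                                             exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    s_rank <- rank(scores[, j])
    r_xy <- stats::cor(s_rank, out_rank)
    r_xz <- stats::cor(s_rank, dia_rank)
    r_yz <- stats::cor(out_rank, dia_rank)
    rows[[length(rows) + 1]] <- data.frame(
      component = paste0("PC", j), covariate = cv, rho = rho, p_value = p,
      partial_rho_outcome_given_diagnosis = partial_cor(r_xy, r_xz, r_yz))
  }
  list(scores = scores, explained = explained,
       correlations = do.call(rbind, rows))
}
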