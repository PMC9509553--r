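# Core domain containers. Lightweight S3: validated lists / data.frames, in
# the style of simple Bioconductor-adjacent analysis packages.

#' Construct an expression matrix container
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param size_factors optional positive numeric vector, one per sample.
#' @param normalized optional numeric matrix of size-factor normalized counts.
#' @return An object of class `expression_matrix` with elements `counts`,
#'   `size_factors`, `normalized`.
#' @export
expression_matrix <- function(counts, size_factors = NULL, normalized = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_tnf("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop_tnf("duplicate gene ids: %s",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_tnf("counts must be non-negative integers; offending gene '%s', sample '%s'",
             rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  storage.mode(counts) <- "integer"
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts))
      stop_tnf("size_factors length %d does not match %d samples",
               length(size_factors), ncol(counts))
    if (any(size_factors <= 0)) stop_tnf("size_factors must be positive")
  }
  structure(list(counts = counts, size_factors = size_factors,
                 normalized = normalized),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%snormalized)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "not " else ""))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Construct a methylation matrix container
#'
#' @param beta numeric matrix of beta values in \[0, 1\] (NA allowed), probes x
#'   samples, with row and column names.
#' @param annotation data.frame with columns `probe_id`, `chrom`, `pos`
#'   (0-based) and logical flags `snp_overlap`, `unreliable`,
#'   `context_specific`; one row per probe of `beta`.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, annotation) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop_tnf("beta must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(beta)))
    stop_tnf("duplicate probe ids in beta matrix")
  out <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(out) > 0)
    stop_tnf("beta values must lie in [0, 1]; offending probe '%s' (sample '%s', value %.3g)",
             rownames(beta)[out[1, 1]], colnames(beta)[out[1, 2]],
             beta[out[1, 1], out[1, 2]])
  need <- c("probe_id", "chrom", "pos", "snp_overlap", "unreliable", "context_specific")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0)
    stop_tnf("probe annotation lacks columns: %s", paste(miss, collapse = ", "))
  unannotated <- setdiff(rownames(beta), annotation$probe_id)
  if (length(unannotated) > 0)
    stop_tnf("probes without annotation: %s",
             paste(utils::head(unannotated, 5), collapse = ", "))
  annotation <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(beta = beta, annotation = annotation),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d probes x %d samples (%d missing values)\n",
              nrow(x$beta), ncol(x$beta), sum(is.na(x$beta))))
  invisible(x)
}

#' Construct and validate a cohort design
#'
#' One row per sample of either omics layer. Validates the longitudinal
#' sampling scheme: `(patient_id, timepoint, assay)` unique; outcome group,
#' diagnosis and treatment constant within patient; methylation sampled only at
#' baseline, week 2 and week 6.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `assay`
#'   (`rna`/`methylation`), `timepoint`, `group` (`remission`/`non_remission`),
#'   `diagnosis` (`CD`/`UC`), `treatment` (`anti_tnf`/`vedolizumab`), plus
#'   optional numeric clinical covariates (e.g. `CRP`, `activity_score`, `IL6`,
#'   `fecal_calprotectin`, `leukocytes`, `tryptophan`). Missing covariate
#'   values are allowed and propagated.
#' @return The validated data.frame with class `cohort_design`; `timepoint` is
#'   an ordered factor and a numeric `hours` column is added.
#' @export
cohort_design <- function(df) {
  need <- c("sample_id", "patient_id", "assay", "timepoint", "group",
            "diagnosis", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_tnf("design lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_tnf("duplicate sample ids: %s",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_tp <- setdiff(unique(df$timepoint), timepoint_levels())
  if (length(bad_tp) > 0)
    stop_tnf("unknown timepoint label(s): %s", paste(bad_tp, collapse = ", "))
  bad_assay <- setdiff(unique(df$assay), c("rna", "methylation"))
  if (length(bad_assay) > 0)
    stop_tnf("unknown assay label(s): %s", paste(bad_assay, collapse = ", "))
  bad_grp <- setdiff(unique(df$group), c("remission", "non_remission"))
  if (length(bad_grp) > 0)
    stop_tnf("unknown group label(s): %s", paste(bad_grp, collapse = ", "))
  key <- paste(df$patient_id, df$timepoint, df$assay)
  if (anyDuplicated(key))
    stop_tnf("duplicate (patient, timepoint, assay): %s",
             key[duplicated(key)][1])
  for (col in c("group", "diagnosis", "treatment")) {
    per <- tapply(df[[col]], df$patient_id, function(v) length(unique(v)))
    if (any(per > 1))
      stop_tnf("patient '%s' has inconsistent %s", names(per)[per > 1][1], col)
  }
  meth_bad <- df$assay == "methylation" & !(df$timepoint %in% methylation_timepoints())
  if (any(meth_bad))
    stop_tnf("methylation sample '%s' at timepoint '%s' outside the methylation scheme",
             df$sample_id[meth_bad][1], df$timepoint[meth_bad][1])
  df$timepoint <- factor(df$timepoint, levels = timepoint_levels(), ordered = TRUE)
  df$hours <- unname(timepoint_hours()[as.character(df$timepoint)])
  class(df) <- c("cohort_design", "data.frame")
  df
}

# Subset a design to one assay, optionally one group / timepoint set.
design_subset <- function(design, assay = NULL, group = NULL, timepoints = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(assay)) keep <- keep & design$assay == assay
  if (!is.null(group)) keep <- keep & design$group %in% group
  if (!is.null(timepoints)) keep <- keep & as.character(design$timepoint) %in% timepoints
  design[keep, , drop = FALSE]
}

#' Construct a gene TSS annotation
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`)
#'   and `tss` (0-based position).
#' @return Validated data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_tnf("gene annotation lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop_tnf("duplicate gene ids in annotation")
  if (!all(df$strand %in% c("+", "-")))
    stop_tnf("strand must be '+' or '-'")
  if (any(df$tss < 0)) stop_tnf("tss positions must be non-negative")
  class(df) <- c("gene_annotation", "data.frame")
  df
}
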