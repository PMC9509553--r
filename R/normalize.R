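# Median-of-ratios normalization.

#' Estimate size factors by the median-of-ratios method
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio between the gene's count in that sample and the gene's geometric mean
#' count across samples. Reference genes are those with a positive geometric
#' mean, i.e. no zero count in any sample.
#'
#' @param expr an [expression_matrix()] or a counts matrix.
#' @return Numeric vector of positive size factors, one per sample, named by
#'   sample id.
#' @export
estimate_size_factors <- function(expr) {
  counts <- if (inherits(expr, "expression_matrix")) expr$counts else as.matrix(expr)
  log_geo <- rowMeans(log(counts))          # -Inf for genes with any zero
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop_tnf("no gene with a positive geometric mean count; cannot normalize")
  ratios <- exp(log(counts[ref, , drop = FALSE]) - log_geo[ref])
  sf <- apply(ratios, 2, stats::median)   # median on the ratio scale
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param expr an [expression_matrix()].
#' @param size_factors positive numeric vector, one per sample; defaults to
#'   [estimate_size_factors()] of `expr`.
#' @return The [expression_matrix()] with its `size_factors` and `normalized`
#'   slots filled (`normalized[g, s] = counts[g, s] / size_factors[s]`).
#' @export
normalize_counts <- function(expr, size_factors = NULL) {
  if (!inherits(expr, "expression_matrix"))
    expr <- expression_matrix(expr)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(expr)
  if (length(size_factors) != ncol(expr$counts))
    stop_tnf("%d size factors for %d samples", length(size_factors),
             ncol(expr$counts))
  if (any(size_factors <= 0)) stop_tnf("size factors must be positive")
  expr$size_factors <- stats::setNames(as.numeric(size_factors),
                                       colnames(expr$counts))
  expr$normalized <- sweep(expr$counts, 2, size_factors, "/")
  expr
}

# log2(x + 1) of normalized counts, the working scale for networks and PCA.
log_normalized <- function(expr) {
  if (is.null(expr$normalized))
    stop_tnf("expression matrix is not normalized; call normalize_counts() first")
  log2(expr$normalized + 1)
}
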