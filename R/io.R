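# File readers and writers. All tabular dialects are TSV with a header row;
# gene annotation travels as BED6 with 0-based half-open coordinates.

#' Read a gene count matrix from TSV
#'
#' First column holds gene ids, the header row sample ids, cells non-negative
#' integers. Row and column order of the file is preserved.
#'
#' @param path path to a TSV file.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop_tnf("count file needs a gene-id column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop_tnf("non-numeric count for gene '%s', sample '%s'",
             ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]])
  }
  rownames(m) <- ids
  expression_matrix(m)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]; the canonical formatting round-trips
#' byte-stably.
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_counts <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a methylation beta matrix plus probe annotation
#'
#' Beta cells are reals in \[0, 1\] or empty (missing). Every probe must appear
#' in the annotation file, which carries `probe_id`, `chrom`, `pos` and the
#' three QC flag columns.
#'
#' @param path TSV of beta values (first column probe ids).
#' @param annotation_path TSV of probe annotation.
#' @return A [methylation_matrix()].
#' @export
read_betas <- function(path, annotation_path) {
  df <- read_tsv(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ann <- read_tsv(annotation_path)
  for (fl in c("snp_overlap", "unreliable", "context_specific"))
    if (fl %in% names(ann)) ann[[fl]] <- as.logical(ann[[fl]])
  methylation_matrix(m, ann)
}

#' Write a methylation matrix (and its annotation) to TSV
#'
#' @param meth a [methylation_matrix()].
#' @param path output path for beta values.
#' @param annotation_path output path for the probe annotation.
#' @export
write_betas <- function(meth, path, annotation_path) {
  df <- data.frame(probe_id = rownames(meth$beta), meth$beta,
                   check.names = FALSE)
  write_tsv(df, path)
  write_tsv(meth$annotation, annotation_path)
}

#' Read a cohort design sheet from TSV
#'
#' @param path TSV with one row per sample; see [cohort_design()] for the
#'   required columns and invariants.
#' @return A validated [cohort_design()].
#' @export
read_design <- function(path) {
  cohort_design(read_tsv(path))
}

#' Write a cohort design to TSV
#' @param design a [cohort_design()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design)
  df$timepoint <- as.character(df$timepoint)
  df$hours <- NULL
  write_tsv(df, path)
}

#' Read gene transcription start sites from BED6
#'
#' Coordinates are 0-based half-open. The TSS is `start` on the "+" strand and
#' `end - 1` on the "-" strand.
#'
#' @param path BED6 file (chrom, start, end, gene_id, score, strand; no
#'   header).
#' @return A [gene_annotation()].
#' @export
read_tss <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "score", "strand"))
  if (!all(df$strand %in% c("+", "-")))
    stop_tnf("BED strand must be '+' or '-', got '%s'",
             setdiff(df$strand, c("+", "-"))[1])
  bad <- df$start >= df$end
  if (any(bad))
    stop_tnf("BED interval with start >= end for gene '%s'", df$gene_id[bad][1])
  gene_annotation(data.frame(
    gene_id = df$gene_id,
    chrom = df$chrom,
    strand = df$strand,
    tss = ifelse(df$strand == "+", df$start, df$end - 1L)
  ))
}

#' Write gene annotation as BED6
#'
#' Emits a 1-bp interval at the TSS, respecting the strand convention of
#' [read_tss()].
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @export
write_tss <- function(ann, path) {
  df <- data.frame(chrom = ann$chrom, start = ann$tss, end = ann$tss + 1L,
                   gene_id = ann$gene_id, score = ".", strand = ann$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
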