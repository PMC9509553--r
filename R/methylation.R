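# Differential methylation: probe QC filtering, combined-rank DMP calling
# between paired timepoints, region aggregation, and annotation-category
# representation tests.

#' Filter methylation probes
#'
#' Removes, in order: SNP-overlapping probes, probes flagged unreliable,
#' context-specific probes, sex-chromosome probes (chrX/chrY), and probes with
#' any missing beta value. Each probe is attributed to the first criterion
#' that removes it.
#'
#' @param meth a [methylation_matrix()].
#' @return The filtered [methylation_matrix()] with attribute `filter_log`, a
#'   data.frame of per-criterion removal counts plus the retained total.
#' @export
filter_probes <- function(meth) {
  ann <- meth$annotation
  removed <- rep(NA_character_, nrow(ann))
  mark <- function(removed, cond, label) {
    ifelse(is.na(removed) & cond, label, removed)
  }
  removed <- mark(removed, ann$snp_overlap %in% TRUE, "snp_overlap")
  removed <- mark(removed, ann$unreliable %in% TRUE, "unreliable")
  removed <- mark(removed, ann$context_specific %in% TRUE, "context_specific")
  removed <- mark(removed, ann$chrom %in% c("chrX", "chrY", "X", "Y"),
                  "sex_chromosome")
  removed <- mark(removed, rowSums(is.na(meth$beta)) > 0, "missing_beta")
  keep <- is.na(removed)
  criteria <- c("snp_overlap", "unreliable", "context_specific",
                "sex_chromosome", "missing_beta")
  log <- data.frame(
    criterion = c(criteria, "retained"),
    n = c(vapply(criteria, function(cr) sum(removed %in% cr), integer(1)),
          sum(keep)))
  out <- methylation_matrix(meth$beta[keep, , drop = FALSE],
                            ann[keep, , drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Combined-rank differential methylation between baseline and a timepoint
#'
#' Within one outcome group, computes per probe the paired (within-patient)
#' beta differences between the test timepoint and baseline, a moderated
#' paired t-test (probe variance shrunk 50/50 toward the grand median variance,
#' reference t with 2(n-1) degrees of freedom), the mean difference, and the
#' log2 quotient of state means (pseudo-count 0.01). Each statistic is ranked
#' (1 = most extreme: largest |difference|, largest |log quotient|, smallest
#' p); the combined rank is their maximum (or mean when
#' `rank_combination = "mean"`). Significance is assigned by
#' [auto_rank_cutoff()].
#'
#' @param meth a filtered [methylation_matrix()].
#' @param design a [cohort_design()].
#' @param group outcome group.
#' @param timepoint test timepoint (`"2w"` or `"6w"`).
#' @param fdr_threshold threshold driving the automatic rank cutoff.
#' @param rank_combination `"max"` (default) or `"mean"`.
#' @return data.frame: probe_id, mean_baseline, mean_test, mean_diff,
#'   log_quotient, p_value, fdr, rank_diff, rank_quot, rank_p, combined_rank,
#'   significant, direction; attribute `rank_cutoff`.
#' @export
dmp_combined_rank <- function(meth, design, group, timepoint,
                              fdr_threshold = 0.05,
                              rank_combination = c("max", "mean")) {
  rank_combination <- match.arg(rank_combination)
  d <- design_subset(design, assay = "methylation", group = group,
                     timepoints = c("baseline", timepoint))
  tab <- table(d$patient_id)
  unpaired <- names(tab)[tab != 2]
  paired <- names(tab)[tab == 2]
  if (length(paired) < 3)
    stop_tnf("combined-rank DMP calling needs >= 3 paired patients; unpaired: %s",
             paste(unpaired, collapse = ", "))
  d <- d[d$patient_id %in% paired, , drop = FALSE]
  base_s <- d$sample_id[match(paste(paired, "baseline"),
                              paste(d$patient_id, d$timepoint))]
  test_s <- d$sample_id[match(paste(paired, timepoint),
                              paste(d$patient_id, d$timepoint))]
  b0 <- meth$beta[, base_s, drop = FALSE]
  b1 <- meth$beta[, test_s, drop = FALSE]
  diffs <- b1 - b0
  n <- length(paired)
  mean_diff <- rowMeans(diffs)
  s2 <- apply(diffs, 1, stats::var)
  s2_mod <- 0.5 * s2 + 0.5 * stats::median(s2, na.rm = TRUE)
  tstat <- mean_diff / sqrt(s2_mod / n)
  p <- 2 * stats::pt(-abs(tstat), df = 2 * (n - 1))
  mean_b0 <- rowMeans(b0)
  mean_b1 <- rowMeans(b1)
  log_quot <- log2((mean_b1 + 0.01) / (mean_b0 + 0.01))
  out <- data.frame(
    probe_id = rownames(meth$beta),
    mean_baseline = mean_b0, mean_test = mean_b1, mean_diff = mean_diff,
    log_quotient = log_quot, p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    rank_diff = rank(-abs(mean_diff), ties.method = "min"),
    rank_quot = rank(-abs(log_quot), ties.method = "min"),
    rank_p = rank(p, ties.method = "min"),
    stringsAsFactors = FALSE)
  out$combined_rank <- if (rank_combination == "max")
    pmax(out$rank_diff, out$rank_quot, out$rank_p)
  else
    as.integer(round(rowMeans(out[, c("rank_diff", "rank_quot", "rank_p")])))
  out$direction <- ifelse(out$mean_diff >= 0, "hyper", "hypo")
  cutoff <- auto_rank_cutoff(out, fdr_threshold)
  out$significant <- out$combined_rank <= cutoff
  rownames(out) <- NULL
  attr(out, "rank_cutoff") <- cutoff
  attr(out, "contrast") <- sprintf("%s_vs_baseline.%s", timepoint, group)
  out
}

#' Automatic combined-rank cutoff
#'
#' The cutoff `r*` is the number of probes whose Benjamini-Hochberg adjusted
#' p-value falls below the FDR threshold; probes with `combined_rank <= r*`
#' are significant. `r* = 0` (no significant probe) is allowed.
#'
#' @param dmps a [dmp_combined_rank()] table (needs `p_value`).
#' @param fdr_threshold FDR level.
#' @return Integer cutoff.
#' @export
auto_rank_cutoff <- function(dmps, fdr_threshold = 0.05) {
  if (nrow(dmps) == 0) stop_tnf("empty DMP table")
  fdr <- stats::p.adjust(dmps$p_value, method = "BH")
  sum(fdr < fdr_threshold, na.rm = TRUE)
}

#' Aggregate DMPs into differentially methylated regions
#'
#' A region's score is the mean combined rank of its member probes (those
#' surviving the probe filter); regions with at least 2 members and a score at
#' or below the rank cutoff are significant. Regions left with no surviving
#' probes are dropped with a warning; single-probe regions are never
#' significant and are flagged.
#'
#' @param dmps a [dmp_combined_rank()] table (carries the rank cutoff).
#' @param region_map data.frame: region_id, region_class (promoter, gene,
#'   cpg_island, enhancer), probe_id.
#' @return data.frame: region_id, region_class, n_probes, region_score,
#'   significant, single_probe.
#' @export
dmr_aggregate <- function(dmps, region_map) {
  cutoff <- attr(dmps, "rank_cutoff")
  if (is.null(cutoff)) stop_tnf("dmps table lacks a rank_cutoff attribute")
  region_map <- region_map[region_map$probe_id %in% dmps$probe_id, , drop = FALSE]
  all_regions <- unique(region_map$region_id)
  rows <- lapply(split(region_map, region_map$region_id), function(rm) {
    ranks <- dmps$combined_rank[match(rm$probe_id, dmps$probe_id)]
    data.frame(region_id = rm$region_id[1], region_class = rm$region_class[1],
               n_probes = nrow(rm), region_score = mean(ranks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no region retained any surviving probe")
    return(data.frame(region_id = character(0), region_class = character(0),
                      n_probes = integer(0), region_score = numeric(0),
                      significant = logical(0), single_probe = logical(0)))
  }
  out$single_probe <- out$n_probes < 2
  out$significant <- !out$single_probe & out$region_score <= cutoff
  rownames(out) <- NULL
  out
}

#' Over/under-representation of significant DMPs in annotation categories
#'
#' For each category, compares the significant-probe count against the
#' expectation under uniform draw from the probe universe with a chi-square
#' test on the 2x2 table (significant yes/no x in-category yes/no).
#'
#' @param significant_probes character vector of significant probe ids.
#' @param universe character vector of all tested probe ids.
#' @param categories named list of probe-id vectors, one per category.
#' @return data.frame: category, n_category, observed, expected, ratio,
#'   chisq_statistic, p_value.
#' @export
region_representation_test <- function(significant_probes, universe, categories) {
  n_sig <- length(intersect(significant_probes, universe))
  rows <- list()
  for (nm in names(categories)) {
    cat_probes <- intersect(categories[[nm]], universe)
    if (length(cat_probes) == 0) {
      warning(sprintf("category '%s' is empty; skipped", nm))
      next
    }
    obs <- length(intersect(significant_probes, cat_probes))
    expd <- n_sig * length(cat_probes) / length(universe)
    tab <- matrix(c(obs, n_sig - obs,
                    length(cat_probes) - obs,
                    length(universe) - length(cat_probes) - (n_sig - obs)),
                  nrow = 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[nm]] <- data.frame(
      category = nm, n_category = length(cat_probes), observed = obs,
      expected = expd, ratio = if (expd > 0) obs / expd else NA_real_,
      chisq_statistic = unname(ct$statistic), p_value = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
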