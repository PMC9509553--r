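# Permutation Z-summary module preservation: density and connectivity
# statistics of reference modules evaluated in test data, standardized against
# random same-size gene sets. A 4-statistic subset of the published
# preservation suite (two density, two connectivity statistics).

# Observed preservation statistics of gene set `idx` given precomputed
# reference and test correlation and adjacency matrices.
preservation_stats <- function(idx, cor_ref, cor_test, adj_test, adj_ref) {
  sub_ct <- cor_test[idx, idx, drop = FALSE]
  sub_cr <- cor_ref[idx, idx, drop = FALSE]
  off <- upper.tri(sub_ct)
  d1 <- mean(sub_ct[off])                           # mean intramodule correlation
  d2 <- mean(adj_test[idx, idx][off])               # mean intramodule adjacency
  kim_ref <- rowSums(adj_ref[idx, idx, drop = FALSE]) - 1
  kim_test <- rowSums(adj_test[idx, idx, drop = FALSE]) - 1
  c1 <- suppressWarnings(stats::cor(kim_ref, kim_test))   # cor of kIM
  c2 <- suppressWarnings(stats::cor(sub_cr[off], sub_ct[off]))  # cor of cor patterns
  c(d1 = d1, d2 = d2, c1 = c1, c2 = c2)
}

classify_preservation <- function(z) {
  ifelse(z < 2, "not_preserved", ifelse(z <= 10, "moderate", "high"))
}

#' Permutation Z-summary preservation of reference modules in test data
#'
#' For each reference module, computes in the test data two density statistics
#' (mean intramodule correlation, mean intramodule signed adjacency) and two
#' connectivity statistics (correlation of intramodular connectivity between
#' reference and test; correlation of the vectorized intramodule correlation
#' matrices). Each statistic is standardized against `n_permutations` random
#' gene sets of the same size drawn from the test universe. `z_density` and
#' `z_connectivity` are the medians of their statistic sets and `z_summary`
#' their mean. Modules classify as not preserved (`z_summary < 2`), moderate
#' (2 to 10, boundaries included) or high (`> 10`).
#'
#' @param ref_modules a `module_set` built on the reference data.
#' @param ref_expr_log reference expression (genes x samples, log scale).
#' @param test_expr_log test expression covering the module genes.
#' @param n_permutations random gene sets per module (>= 50).
#' @param seed integer seed for the permutation draw.
#' @param power soft power for adjacencies; defaults to the reference power.
#' @return data.frame: module, module_size, z_density, z_connectivity,
#'   z_summary, preservation_class.
#' @export
preservation_zsummary <- function(ref_modules, ref_expr_log, test_expr_log,
                                  n_permutations = 100, seed = 1,
                                  power = NULL) {
  if (n_permutations < 50)
    stop_tnf("n_permutations must be >= 50, got %d", n_permutations)
  power <- power %||% ref_modules$power
  membership <- ref_modules$membership
  mods <- setdiff(sort(unique(membership)), "unassigned")
  mods <- mods[order(as.numeric(sub("^M", "", mods)))]
  missing_genes <- setdiff(names(membership), rownames(test_expr_log))
  if (length(missing_genes) > 0)
    stop_tnf("module genes missing from test data: %s",
             paste(utils::head(missing_genes, 5), collapse = ", "))
  universe <- intersect(rownames(test_expr_log), rownames(ref_expr_log))
  cor_ref <- network_correlation(ref_expr_log[universe, , drop = FALSE])
  cor_test <- network_correlation(test_expr_log[universe, , drop = FALSE])
  adj_ref <- signed_adjacency(cor_ref, power)
  adj_test <- signed_adjacency(cor_test, power)

  with_seed(seed, {
    rows <- lapply(mods, function(m) {
      genes <- intersect(names(membership)[membership == m], universe)
      idx <- match(genes, universe)
      obs <- preservation_stats(idx, cor_ref, cor_test, adj_test, adj_ref)
      null_mat <- vapply(seq_len(n_permutations), function(i) {
        ridx <- sample(length(universe), length(idx))
        preservation_stats(ridx, cor_ref, cor_test, adj_test, adj_ref)
      }, numeric(4))
      mu <- rowMeans(null_mat, na.rm = TRUE)
      sdv <- apply(null_mat, 1, stats::sd, na.rm = TRUE)
      z <- (obs - mu) / sdv
      bad <- !is.finite(z)
      if (any(bad)) {
        warning(sprintf("module %s: statistic(s) %s skipped (zero null sd or undefined)",
                        m, paste(names(obs)[bad], collapse = ",")))
        z <- z[!bad]
      }
      zd <- stats::median(z[names(z) %in% c("d1", "d2")])
      zc <- stats::median(z[names(z) %in% c("c1", "c2")])
      zs <- mean(c(zd, zc))
      data.frame(module = m, module_size = length(genes),
                 z_density = zd, z_connectivity = zc, z_summary = zs,
                 preservation_class = classify_preservation(zs),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Contrast module preservation between outcome groups
#'
#' Joins per-condition preservation tables (each carrying `condition` and
#' `timepoint` columns, as produced by the pipeline) and flags modules whose
#' preservation class in non-remission strictly exceeds that in remission
#' (ordering not_preserved < moderate < high) at one or more timepoints --
#' i.e. modules disrupted specifically in remitting patients.
#'
#' @param results_remission,results_non_remission [preservation_zsummary()]
#'   tables with a `timepoint` column.
#' @return data.frame: module, timepoint, class_remission, class_non_remission,
#'   differential (per row), flagged (per module, any timepoint).
#' @export
contrast_preservation <- function(results_remission, results_non_remission) {
  key <- c("module", "timepoint")
  a <- results_remission; b <- results_non_remission
  if (!setequal(paste(a$module, a$timepoint), paste(b$module, b$timepoint)))
    stop_tnf("preservation tables cover different module/timepoint sets")
  m <- merge(a[, c(key, "z_summary", "preservation_class")],
             b[, c(key, "z_summary", "preservation_class")],
             by = key, suffixes = c("_remission", "_non_remission"))
  lev <- c("not_preserved", "moderate", "high")
  m$differential <- match(m$preservation_class_non_remission, lev) >
    match(m$preservation_class_remission, lev)
  flagged <- tapply(m$differential, m$module, any)
  m$flagged <- unname(flagged[m$module])
  m[order(m$module, m$timepoint), , drop = FALSE]
}

#' Per-gene kME shift between baseline and post-treatment data
#'
#' Recomputes, for each reference module, eigengenes on the reference gene
#' membership within the baseline data and within each condition's test data,
#' and reports each gene's kME in every dataset plus its kME loss
#' (baseline minus remission test). Genes are ranked by loss within flagged
#' modules when `flagged_modules` is given.
#'
#' @param ref_modules a `module_set` (reference membership).
#' @param expr_baseline baseline expression (log scale, genes x samples).
#' @param expr_test_by_condition named list of test expression matrices, one
#'   per condition (must include `"remission"`).
#' @param flagged_modules optional character vector of modules to rank within.
#' @return data.frame: gene_id, module, kme_baseline, one `kme_<condition>`
#'   column per condition, delta_kme (baseline - remission), rank_in_module.
#' @export
kme_shift <- function(ref_modules, expr_baseline, expr_test_by_condition,
                      flagged_modules = NULL) {
  membership <- ref_modules$membership
  genes <- names(membership)[membership != "unassigned"]
  for (nm in names(expr_test_by_condition)) {
    missing_genes <- setdiff(genes, rownames(expr_test_by_condition[[nm]]))
    if (length(missing_genes) > 0)
      stop_tnf("genes absent from %s test data: %s", nm,
               paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  kme_in <- function(expr_log) {
    ms <- module_eigengenes_and_kme(expr_log[names(membership), , drop = FALSE],
                                    membership)
    ms$kme
  }
  k_base <- kme_in(expr_baseline)
  k_test <- lapply(expr_test_by_condition, kme_in)
  out <- data.frame(gene_id = genes, module = membership[genes],
                    kme_baseline = vapply(genes, function(g)
                      k_base[g, membership[g]], numeric(1)),
                    stringsAsFactors = FALSE)
  for (nm in names(k_test))
    out[[paste0("kme_", nm)]] <- vapply(genes, function(g)
      k_test[[nm]][g, membership[g]], numeric(1))
  if (!"kme_remission" %in% names(out))
    stop_tnf("expr_test_by_condition must include a 'remission' element")
  out$delta_kme <- out$kme_baseline - out$kme_remission
  out$rank_in_module <- stats::ave(-out$delta_kme, out$module,
                                   FUN = function(v) rank(v, ties.method = "first"))
  if (!is.null(flagged_modules))
    out <- out[out$module %in% flagged_modules, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$module, out$rank_in_module), , drop = FALSE]
}
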