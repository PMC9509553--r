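#' Analysis configuration
#'
#' Collects the tunable parameters of the workflow in one validated object.
#' Defaults mirror the study's published settings: FDR 0.05 throughout, signed
#' network soft threshold chosen as the minimum power with scale-free fit above
#' 0.9 (power 16 in the discovery cohort), minimum module size 15, module merge
#' cut height 0.2 on eigengene dissimilarity, a +-5000 bp cis window around the
#' TSS, and 10-fold cross-validation for prediction.
#'
#' @param fdr_threshold significance threshold for Benjamini-Hochberg adjusted
#'   p-values (all stages).
#' @param soft_power_grid candidate soft-threshold powers for the signed
#'   adjacency.
#' @param scale_free_target required scale-free topology fit R^2.
#' @param network_power_fallback power used by the pipeline when no grid
#'   power attains the scale-free target on a focused gene subset (16, the
#'   discovery cohort's signed-network power).
#' @param min_module_size smallest gene count for a named co-expression module.
#' @param merge_cut_height eigengene dissimilarity (1 - cor) below which
#'   modules are merged.
#' @param cis_window_bp half-width of the window around a DEG's transcription
#'   start site within which DMPs are considered cis.
#' @param n_permutations permutations for module preservation and cis FDR.
#' @param cv_folds folds for cross-validated AUC.
#' @param deg_combination how pairwise and longitudinal DEG calls are combined:
#'   `"union"` (default, matching the combined reporting) or `"intersection"`.
#' @param tree_distance distance for the gene tree: `"tom"` (1 - topological
#'   overlap, default) or `"adjacency"` (1 - signed adjacency).
#' @param rank_combination combined-rank rule for differential methylation:
#'   `"max"` (default) or `"mean"`.
#' @param rng_seed integer seed recorded in every output and used to derive
#'   per-stage streams.
#' @return A named list of class `tnf_config`.
#' @export
analysis_config <- function(fdr_threshold = 0.05,
                            soft_power_grid = c(1:10, 12, 14, 16, 18, 20),
                            scale_free_target = 0.9,
                            network_power_fallback = 16L,
                            min_module_size = 15,
                            merge_cut_height = 0.2,
                            cis_window_bp = 5000L,
                            n_permutations = 100L,
                            cv_folds = 10L,
                            deg_combination = c("union", "intersection"),
                            tree_distance = c("tom", "adjacency"),
                            rank_combination = c("max", "mean"),
                            rng_seed = 1L) {
  cfg <- list(
    fdr_threshold = fdr_threshold,
    soft_power_grid = as.integer(soft_power_grid),
    scale_free_target = scale_free_target,
    network_power_fallback = as.integer(network_power_fallback),
    min_module_size = as.integer(min_module_size),
    merge_cut_height = merge_cut_height,
    cis_window_bp = as.integer(cis_window_bp),
    n_permutations = as.integer(n_permutations),
    cv_folds = as.integer(cv_folds),
    deg_combination = match.arg(deg_combination),
    tree_distance = match.arg(tree_distance),
    rank_combination = match.arg(rank_combination),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "tnf_config"
  cfg
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$fdr_threshold) || cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1)
    stop_tnf("fdr_threshold must be in (0, 1), got %s", cfg$fdr_threshold)
  if (length(cfg$soft_power_grid) < 1 || any(cfg$soft_power_grid < 1))
    stop_tnf("soft_power_grid must be non-empty positive integers")
  if (cfg$scale_free_target <= 0 || cfg$scale_free_target > 1)
    stop_tnf("scale_free_target must be in (0, 1]")
  if (cfg$network_power_fallback < 1)
    stop_tnf("network_power_fallback must be a positive integer")
  if (cfg$min_module_size < 2)
    stop_tnf("min_module_size must be at least 2")
  if (cfg$merge_cut_height < 0 || cfg$merge_cut_height > 1)
    stop_tnf("merge_cut_height must be in [0, 1]")
  if (cfg$cis_window_bp < 0)
    stop_tnf("cis_window_bp must be non-negative")
  if (cfg$n_permutations < 1)
    stop_tnf("n_permutations must be positive")
  if (cfg$cv_folds < 2)
    stop_tnf("cv_folds must be at least 2, got %d", cfg$cv_folds)
  if (is.na(cfg$rng_seed))
    stop_tnf("rng_seed must be an integer")
  invisible(cfg)
}

# Stable hash of a configuration, recorded as provenance in pipeline outputs.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
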