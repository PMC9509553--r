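# End-to-end pipeline: normalize -> differential expression -> network ->
# preservation -> differential methylation -> cis integration -> prediction.
# Every stage writes a TSV under the output directory; a structured log
# records the seed, configuration hash and per-stage status.

pipeline_log <- function(log_path, stage, status, detail = "") {
  line <- sprintf("%s\t%s\t%s", stage, status, detail)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}

#' Run the full multi-omics analysis pipeline
#'
#' Executes, in order: (1) median-of-ratios normalization; (2) pairwise DE at
#' every post-baseline timepoint and impulse-model longitudinal DE, per
#' outcome group, combined into DEG sets; (3) signed co-expression network on
#' the remission DEGs at baseline; (4) Z-summary preservation of the baseline
#' modules at weeks 2 and 6 per group, the remission/non-remission contrast
#' and the kME shift ranking; (5) probe filtering and combined-rank DMP
#' calling per group at weeks 2 and 6; (6) cis DMP-DEG mapping, Spearman
#' correlation, permutation FDR and sign classification plus module
#' over-representation; (7) random-forest prediction of remission from the
#' DNAm-linked DEGs at baseline + week 2 with cross-validated AUC. A rerun
#' with the same seed and inputs is byte-identical.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory for stage TSVs, log and summary.
#' @param cohort a `sim_cohort`-shaped list (`expr`, `meth`, `design`,
#'   `annotation`); if `NULL`, a cohort is simulated from `sim` with the
#'   config's seed.
#' @param sim a [sim_config()] used when `cohort` is `NULL`.
#' @return Invisibly, a list with all in-memory stage outputs (`expr`,
#'   `pairwise`, `longitudinal`, `deg_sets`, `modules`, `preservation`,
#'   `preservation_contrast`, `kme_shift`, `dmps`, `cis_pairs`, `signs`,
#'   `module_enrichment`, `prediction`, `truth` when simulated).
#' @export
run_pipeline <- function(config = analysis_config(), out_dir,
                         cohort = NULL, sim = sim_config()) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.tsv")
  cat("stage\tstatus\tdetail\n", file = log_path)
  pipeline_log(log_path, "provenance", "info",
               sprintf("seed=%d config_md5=%s", config$rng_seed,
                       config_hash(config)))
  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) {
      pipeline_log(log_path, stage, "failed", conditionMessage(e))
      stop_tnf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
    pipeline_log(log_path, stage, "ok", "")
    res
  }
  out <- list()

  if (is.null(cohort)) {
    cohort <- run_stage("simulate", function()
      simulate_cohort(sim, seed = config$rng_seed))
    out$truth <- cohort$truth
  }
  expr <- cohort$expr; meth <- cohort$meth
  design <- cohort$design; annotation <- cohort$annotation
  out$design <- design
  out$annotation <- annotation

  ## normalize ---------------------------------------------------------------
  expr <- run_stage("normalize", function() normalize_counts(expr))
  out$expr <- expr
  write_tsv(data.frame(sample_id = names(expr$size_factors),
                       size_factor = unname(expr$size_factors)),
            file.path(out_dir, "size_factors.tsv"))

  ## differential expression -------------------------------------------------
  groups <- c("remission", "non_remission")
  post_tps <- setdiff(timepoint_levels(), "baseline")
  de <- run_stage("de", function() {
    pw <- list(); lg <- list()
    for (grp in groups) {
      pw[[grp]] <- lapply(post_tps, function(tp)
        pairwise_de(expr, design, grp, tp))
      names(pw[[grp]]) <- post_tps
      lg[[grp]] <- longitudinal_de(expr, design, grp)
    }
    list(pairwise = pw, longitudinal = lg)
  })
  out$pairwise <- de$pairwise
  out$longitudinal <- de$longitudinal
  out$deg_sets <- lapply(groups, function(grp)
    combine_deg_sets(de$pairwise[[grp]], de$longitudinal[[grp]],
                     fdr_threshold = config$fdr_threshold,
                     mode = config$deg_combination))
  names(out$deg_sets) <- groups
  for (grp in groups) {
    write_tsv(do.call(rbind, de$pairwise[[grp]]),
              file.path(out_dir, sprintf("de_pairwise_%s.tsv", grp)))
    write_tsv(de$longitudinal[[grp]],
              file.path(out_dir, sprintf("de_longitudinal_%s.tsv", grp)))
    write_tsv(as.data.frame(out$deg_sets[[grp]]),
              file.path(out_dir, sprintf("deg_set_%s.tsv", grp)))
  }

  ## co-expression network on remission DEGs at baseline ---------------------
  degs_rem <- out$deg_sets$remission$gene_id
  base_samples <- design_subset(design, assay = "rna",
                                timepoints = "baseline")$sample_id
  net <- run_stage("network", function() {
    if (length(degs_rem) < 2 * config$min_module_size)
      stop_tnf("too few remission DEGs (%d) for network construction",
               length(degs_rem))
    x <- log_normalized(expr)[degs_rem, base_samples, drop = FALSE]
    power <- pick_soft_threshold(x, config$soft_power_grid,
                                 config$scale_free_target)
    if (!attr(power, "target_reached")) power <- config$network_power_fallback
    ms <- detect_modules(x, as.integer(power), config$min_module_size,
                         tree_distance = config$tree_distance)
    ms <- merge_close_modules(ms, x, config$merge_cut_height)
    list(modules = ms, expr_baseline = x)
  })
  out$modules <- net$modules
  write_tsv(data.frame(gene_id = names(net$modules$membership),
                       module = unname(net$modules$membership)),
            file.path(out_dir, "modules.tsv"))
  if (!is.null(net$modules$eigengenes)) {
    write_tsv(data.frame(module = rownames(net$modules$eigengenes),
                         net$modules$eigengenes, check.names = FALSE),
              file.path(out_dir, "eigengenes.tsv"))
    mtc <- module_trait_correlation(net$modules$eigengenes, design,
                                    c("CRP", "IL6", "activity_score",
                                      "fecal_calprotectin", "leukocytes"))
    write_tsv(mtc, file.path(out_dir, "module_trait_correlation.tsv"))
    out$module_trait <- mtc
  }

  ## module preservation ------------------------------------------------------
  pres <- run_stage("preserve", function() {
    xlog <- log_normalized(expr)
    rows <- list()
    for (grp in groups) for (tp in c("2w", "6w")) {
      smp <- design_subset(design, assay = "rna", group = grp,
                           timepoints = tp)$sample_id
      tab <- preservation_zsummary(
        net$modules, net$expr_baseline,
        xlog[degs_rem, smp, drop = FALSE],
        n_permutations = config$n_permutations,
        seed = child_seed(config$rng_seed, paste0("pres", grp, tp)))
      tab$condition <- grp
      tab$timepoint <- tp
      rows[[paste(grp, tp)]] <- tab
    }
    do.call(rbind, rows)
  })
  rownames(pres) <- NULL
  out$preservation <- pres
  write_tsv(pres, file.path(out_dir, "preservation.tsv"))
  out$preservation_contrast <- run_stage("preserve_contrast", function()
    contrast_preservation(pres[pres$condition == "remission", ],
                          pres[pres$condition == "non_remission", ]))
  write_tsv(out$preservation_contrast,
            file.path(out_dir, "preservation_contrast.tsv"))
  out$kme_shift <- run_stage("kme_shift", function() {
    xlog <- log_normalized(expr)
    tests <- lapply(stats::setNames(groups, groups), function(grp) {
      smp <- design_subset(design, assay = "rna", group = grp,
                           timepoints = c("2w", "6w"))$sample_id
      xlog[degs_rem, smp, drop = FALSE]
    })
    kme_shift(net$modules, net$expr_baseline, tests)
  })
  write_tsv(out$kme_shift, file.path(out_dir, "kme_shift.tsv"))

  ## differential methylation -------------------------------------------------
  meth_f <- run_stage("filter_probes", function() filter_probes(meth))
  write_tsv(attr(meth_f, "filter_log"), file.path(out_dir, "probe_filter_log.tsv"))
  out$dmps <- run_stage("dmp", function() {
    res <- list()
    for (grp in groups) for (tp in c("2w", "6w")) {
      tab <- dmp_combined_rank(meth_f, design, grp, tp,
                               fdr_threshold = config$fdr_threshold,
                               rank_combination = config$rank_combination)
      res[[sprintf("%s_%s", grp, tp)]] <- tab
    }
    res
  })
  for (nm in names(out$dmps))
    write_tsv(out$dmps[[nm]], file.path(out_dir, sprintf("dmp_%s.tsv", nm)))

  ## cis integration -----------------------------------------------------------
  cis <- run_stage("integrate", function() {
    sig_probes <- unique(c(
      out$dmps$remission_2w$probe_id[out$dmps$remission_2w$significant],
      out$dmps$remission_6w$probe_id[out$dmps$remission_6w$significant]))
    if (length(sig_probes) == 0)
      stop_tnf("no significant remission DMPs to integrate")
    ann_p <- meth_f$annotation[meth_f$annotation$probe_id %in% sig_probes,
                               c("probe_id", "chrom", "pos")]
    pairs <- map_cis_pairs(ann_p, degs_rem, annotation, config$cis_window_bp)
    if (nrow(pairs) == 0) stop_tnf("no candidate cis pairs in the window")
    pairs <- correlate_pairs(expr, meth_f, pairs, design)
    permutation_fdr(pairs, expr, meth_f, design,
                    n_permutations = max(100L, config$n_permutations),
                    seed = child_seed(config$rng_seed, "cisperm"),
                    fdr_threshold = config$fdr_threshold)
  })
  out$cis_pairs <- cis
  write_tsv(cis, file.path(out_dir, "cis_pairs.tsv"))
  out$signs <- run_stage("signs", function() classify_signs(cis))
  write_tsv(out$signs$pairs, file.path(out_dir, "cis_sign_summary.tsv"))
  out$module_enrichment <- run_stage("module_enrichment", function()
    module_overrepresentation(unique(cis$gene_id[isTRUE_vec(cis$significant)]),
                              out$modules))
  if (!is.null(out$module_enrichment))
    write_tsv(out$module_enrichment,
              file.path(out_dir, "module_overrepresentation.tsv"))

  ## prediction ----------------------------------------------------------------
  out$prediction <- run_stage("predict", function() {
    linked <- unique(cis$gene_id[isTRUE_vec(cis$significant)])
    genes <- if (length(linked) >= 2) linked else degs_rem
    fm <- assemble_features(design, expr = expr, genes = genes)
    cv_auc(fm, k_folds = config$cv_folds,
           seed = child_seed(config$rng_seed, "cv"))
  })
  write_tsv(out$prediction$roc, file.path(out_dir, "prediction_roc.tsv"))
  write_tsv(data.frame(metric = c("auc", "n_patients", "k_folds"),
                       value = c(out$prediction$auc,
                                 out$prediction$n_patients,
                                 out$prediction$k_folds)),
            file.path(out_dir, "prediction_summary.tsv"))

  ## summary -------------------------------------------------------------------
  summary <- data.frame(
    quantity = c("n_deg_remission", "n_deg_non_remission", "n_modules",
                 "n_disrupted_flagged", "n_significant_cis",
                 "frac_negative_cis", "prediction_auc"),
    value = c(length(out$deg_sets$remission$gene_id),
              length(out$deg_sets$non_remission$gene_id),
              length(setdiff(unique(out$modules$membership), "unassigned")),
              length(unique(out$preservation_contrast$module[
                out$preservation_contrast$flagged])),
              sum(isTRUE_vec(cis$significant)),
              out$signs$pairs$frac_negative,
              out$prediction$auc))
  write_tsv(summary, file.path(out_dir, "summary.tsv"))
  pipeline_log(log_path, "summary", "ok", "complete")
  invisible(out)
}
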