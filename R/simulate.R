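# Synthetic longitudinal two-omics cohort with planted ground truth: impulse
# differential expression, latent-factor co-expression modules disrupted
# post-treatment in remitters, persistent/transient DMPs, cis-coupled
# CpG-gene pairs and outcome-predictive baseline/week-2 features.

#' Simulation parameters
#'
#' Defaults emulate the discovery cohort's statistical structure: 12 patients
#' per outcome group sampled at 7 RNA and 3 methylation timepoints; 2000 genes
#' of which 300 carry impulse-shaped differential expression (200
#' remission-specific, 100 shared); 6 latent-factor co-expression modules of
#' 50 genes partitioning the remission DEGs, 2 of them disrupted (loadings
#' attenuated x0.1) at weeks 2 and 6 in remitters only; 5000 probes with 400
#' planted DMPs (200 persistent in remitters at weeks 2 and 6, 200 transient
#' in non-remitters at week 2 only); 150 cis-coupled CpG-gene pairs (100
#' negative, 50 positive, coupling 0.7 on the latent scale); 30
#' outcome-predictive genes shifted between groups at baseline and week 2.
#'
#' @param n_per_group patients per outcome group.
#' @param n_genes,n_probes matrix dimensions.
#' @param n_modules,module_size,n_disrupted module structure.
#' @param n_de,n_de_remission_specific planted DE genes.
#' @param n_dmps planted DMPs (half persistent/remission, half
#'   transient/non-remission).
#' @param n_cis,n_cis_negative planted cis pairs and their negative subset.
#' @param n_predictive predictive genes.
#' @param dispersion_range NB dispersion range (uniform).
#' @param beta_noise_sd methylation noise sd on the logit (M-value) scale.
#' @param lfc_range peak |log2 fold change| range of planted impulse genes.
#' @param loading_range module factor loadings (log-scale) range.
#' @param attenuation loading multiplier in disrupted modules post-treatment.
#' @param dmp_delta_beta target |delta beta| of planted DMPs.
#' @param cis_coupling latent-scale coupling of cis probes to expression.
#' @param predictive_shift log-scale group offset of predictive genes.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 12, n_genes = 2000, n_probes = 5000,
                       n_modules = 6, module_size = 50, n_disrupted = 2,
                       n_de = 450, n_de_remission_specific = 300,
                       n_dmps = 400, n_cis = 150, n_cis_negative = 100,
                       n_predictive = 30,
                       dispersion_range = c(0.1, 0.5),
                       beta_noise_sd = 0.3,
                       lfc_range = c(1.5, 3),
                       loading_range = c(0.6, 0.9),
                       attenuation = 0.1,
                       dmp_delta_beta = 0.2,
                       cis_coupling = 0.7,
                       predictive_shift = 1.0) {
  cfg <- as.list(environment())
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop_tnf("module genes (%d x %d) exceed n_genes (%d)",
             cfg$n_modules, cfg$module_size, cfg$n_genes)
  if (cfg$n_modules * cfg$module_size > cfg$n_de)
    stop_tnf("modules must fit within the planted DE genes (%d x %d > %d)",
             cfg$n_modules, cfg$module_size, cfg$n_de)
  if (cfg$n_de > cfg$n_genes) stop_tnf("n_de exceeds n_genes")
  if (cfg$n_cis > cfg$n_de)
    stop_tnf("cis pairs requested (%d) exceed planted DE genes (%d)",
             cfg$n_cis, cfg$n_de)
  if (cfg$n_cis_negative > cfg$n_cis) stop_tnf("n_cis_negative > n_cis")
  if (cfg$n_dmps < cfg$n_cis)
    stop_tnf("planted DMPs (%d) must cover the cis probes (%d)",
             cfg$n_dmps, cfg$n_cis)
  if (cfg$n_dmps %% 2 != 0) stop_tnf("n_dmps must be even (group split)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a longitudinal two-omics cohort with planted truth
#'
#' Counts are negative binomial with lognormal library sizes; gene log-means
#' combine a lognormal baseline, per-module latent factors (attenuated at
#' weeks 2 and 6 in remitters for disrupted modules), impulse-shaped treatment
#' responses for DE genes, and constant group offsets for predictive genes.
#' Betas are logistic transforms of Gaussian M-values with planted group x
#' time shifts; cis probes' M-value noise is coupled to their gene's
#' standardized log-expression residual with the planted sign. Identical
#' seeds give identical outputs.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List of class `sim_cohort`: `expr` ([expression_matrix()]), `meth`
#'   ([methylation_matrix()]), `design` ([cohort_design()]), `annotation`
#'   ([gene_annotation()]), `truth` (list of class `ground_truth`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(cfg, seed) {
  n_pat <- 2 * cfg$n_per_group
  patients <- sprintf("P%02d", seq_len(n_pat))
  group <- rep(c("remission", "non_remission"), each = cfg$n_per_group)
  # balance diagnosis within group so group and diagnosis are not confounded
  diagnosis <- unlist(lapply(seq_len(2), function(i)
    rep_len(c("CD", "UC"), cfg$n_per_group)))
  names(group) <- names(diagnosis) <- patients

  rna_tps <- timepoint_levels()
  meth_tps <- methylation_timepoints()
  design <- rbind(
    data.frame(sample_id = paste0("R_", rep(patients, each = length(rna_tps)),
                                  "_", rep(rna_tps, n_pat)),
               patient_id = rep(patients, each = length(rna_tps)),
               assay = "rna",
               timepoint = rep(rna_tps, n_pat), stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("M_", rep(patients, each = length(meth_tps)),
                                  "_", rep(meth_tps, n_pat)),
               patient_id = rep(patients, each = length(meth_tps)),
               assay = "methylation",
               timepoint = rep(meth_tps, n_pat), stringsAsFactors = FALSE))
  design$group <- group[design$patient_id]
  design$diagnosis <- diagnosis[design$patient_id]
  design$treatment <- "anti_tnf"

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  probes <- sprintf("cg%05d", seq_len(cfg$n_probes))

  ## ---- planted gene roles -------------------------------------------------
  de_genes <- genes[seq_len(cfg$n_de)]
  remission_specific <- de_genes[seq_len(cfg$n_de_remission_specific)]
  shared_de <- setdiff(de_genes, remission_specific)
  remission_degs <- de_genes                       # impulse in remitters
  non_remission_degs <- shared_de                  # impulse in both groups
  module_genes <- de_genes[seq_len(cfg$n_modules * cfg$module_size)]
  module_membership <- stats::setNames(
    paste0("M", rep(seq_len(cfg$n_modules), each = cfg$module_size)),
    module_genes)
  disrupted <- paste0("M", seq_len(cfg$n_disrupted))
  predictive <- setdiff(genes, de_genes)[seq_len(cfg$n_predictive)]

  ## ---- per-gene parameters ------------------------------------------------
  base_log_mean <- stats::rnorm(cfg$n_genes, log(100), 1)
  dispersion <- stats::runif(cfg$n_genes, cfg$dispersion_range[1],
                             cfg$dispersion_range[2])
  names(base_log_mean) <- names(dispersion) <- genes

  imp <- data.frame(gene_id = de_genes, stringsAsFactors = FALSE)
  amp_l2 <- stats::runif(cfg$n_de, cfg$lfc_range[1], cfg$lfc_range[2])
  up <- stats::runif(cfg$n_de) < 0.5
  imp$h0 <- 1
  imp$h1 <- ifelse(up, 2^amp_l2, 2^(-amp_l2))
  imp$h2 <- 1
  imp$t1 <- stats::runif(cfg$n_de, 2, 200)
  imp$t2 <- imp$t1 + stats::runif(cfg$n_de, 150, 1500)
  imp$beta_slope <- stats::runif(cfg$n_de, 0.02, 0.1)
  imp$max_abs_log2_effect <- amp_l2
  imp$group_specificity <- ifelse(de_genes %in% remission_specific,
                                  "remission", "shared")

  loadings <- stats::setNames(
    stats::runif(length(module_genes), cfg$loading_range[1],
                 cfg$loading_range[2]), module_genes)
  pred_sign <- stats::setNames(sample(c(-1, 1), cfg$n_predictive, replace = TRUE),
                               predictive)

  ## ---- RNA log-mean matrix ------------------------------------------------
  rna_d <- design[design$assay == "rna", , drop = FALSE]
  hours <- timepoint_hours()[rna_d$timepoint]
  n_rna <- nrow(rna_d)
  lib <- exp(stats::rnorm(n_rna, 0, 0.15))
  log_mu <- matrix(rep(base_log_mean, n_rna), cfg$n_genes, n_rna,
                   dimnames = list(genes, rna_d$sample_id))

  # impulse responses: remission-specific genes only in remitters, shared in
  # both groups; effect is log f(t)/f(0) so baseline levels are untouched
  for (i in seq_len(nrow(imp))) {
    g <- imp$gene_id[i]
    f <- impulse_value(hours, imp$h0[i], imp$h1[i], imp$h2[i],
                       imp$t1[i], imp$t2[i], imp$beta_slope[i])
    f0 <- impulse_value(0, imp$h0[i], imp$h1[i], imp$h2[i],
                        imp$t1[i], imp$t2[i], imp$beta_slope[i])
    eff <- log(f / f0)
    if (imp$group_specificity[i] == "remission")
      eff <- eff * (rna_d$group == "remission")
    log_mu[g, ] <- log_mu[g, ] + eff
  }

  # module latent factors, attenuated in disrupted modules at 2w/6w for
  # remitters only
  factors <- matrix(stats::rnorm(cfg$n_modules * n_rna), cfg$n_modules, n_rna,
                    dimnames = list(paste0("M", seq_len(cfg$n_modules)),
                                    rna_d$sample_id))
  # standardize each factor within every group x timepoint cell so the
  # planted module strength is exactly the configured loading in every
  # condition (not subject to small-sample variance luck)
  cell <- paste(rna_d$group, rna_d$timepoint)
  for (cc in unique(cell)) {
    j <- cell == cc
    if (sum(j) >= 2)
      factors[, j] <- t(scale(t(factors[, j, drop = FALSE])))
  }
  atten_sample <- rna_d$group == "remission" & rna_d$timepoint %in% c("2w", "6w")
  for (g in module_genes) {
    m <- module_membership[g]
    l <- ifelse(m %in% disrupted & atten_sample,
                loadings[g] * cfg$attenuation, loadings[g])
    log_mu[g, ] <- log_mu[g, ] + l * factors[m, ]
  }

  # predictive genes: constant group offset visible at baseline and week 2
  for (g in predictive)
    log_mu[g, ] <- log_mu[g, ] +
      pred_sign[g] * cfg$predictive_shift * (rna_d$group == "remission")

  counts <- matrix(stats::rnbinom(cfg$n_genes * n_rna,
                                  mu = exp(log_mu) * rep(lib, each = cfg$n_genes),
                                  size = rep(1 / dispersion, n_rna)),
                   cfg$n_genes, n_rna,
                   dimnames = list(genes, rna_d$sample_id))

  ## ---- gene annotation ----------------------------------------------------
  chroms <- paste0("chr", 1:5)
  gene_chrom <- rep_len(chroms, cfg$n_genes)
  gene_pos_index <- stats::ave(seq_len(cfg$n_genes), gene_chrom,
                               FUN = seq_along)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  annotation <- gene_annotation(data.frame(
    gene_id = genes, chrom = gene_chrom, strand = strand,
    tss = as.integer(gene_pos_index * 50000L), stringsAsFactors = FALSE))

  ## ---- methylation --------------------------------------------------------
  meth_d <- design[design$assay == "methylation", , drop = FALSE]
  n_meth <- nrow(meth_d)
  # planted DMPs: first half persistent in remitters, second half transient in
  # non-remitters; the cis probes are a subset of the persistent set
  dmp_probes <- probes[seq_len(cfg$n_dmps)]
  persistent <- dmp_probes[seq_len(cfg$n_dmps / 2)]
  transient <- setdiff(dmp_probes, persistent)
  cis_probes <- persistent[seq_len(cfg$n_cis)]
  cis_genes <- de_genes[seq_len(cfg$n_cis)]
  cis_sign <- rep(c(-1, 1), c(cfg$n_cis_negative, cfg$n_cis - cfg$n_cis_negative))

  base_m <- stats::rnorm(cfg$n_probes, 0, 1.5)
  names(base_m) <- probes
  dmp_sign <- stats::setNames(sample(c(-1, 1), cfg$n_dmps, replace = TRUE),
                              dmp_probes)
  # cis probes shift in the canonical orientation: their methylation change
  # mirrors the coupled gene's expression trend with the planted sign, so the
  # mean-level time trend reinforces rather than masks the coupling
  gene_dir_2w <- vapply(seq_len(nrow(imp)), function(i)
    sign(log(impulse_value(336, imp$h0[i], imp$h1[i], imp$h2[i], imp$t1[i],
                           imp$t2[i], imp$beta_slope[i]) /
               impulse_value(0, imp$h0[i], imp$h1[i], imp$h2[i], imp$t1[i],
                             imp$t2[i], imp$beta_slope[i]))), numeric(1))
  names(gene_dir_2w) <- imp$gene_id
  dir_cis <- gene_dir_2w[cis_genes]
  dir_cis[dir_cis == 0] <- 1
  dmp_sign[cis_probes] <- cis_sign * dir_cis
  # logit-scale shift that moves the mean beta by ~dmp_delta_beta
  dmp_shift <- vapply(dmp_probes, function(p) {
    b0 <- sigmoid(base_m[p])
    b1 <- min(max(b0 + dmp_sign[p] * cfg$dmp_delta_beta, 0.03), 0.97)
    logit(b1) - base_m[p]
  }, numeric(1))

  patient_effect <- matrix(stats::rnorm(cfg$n_probes * n_pat, 0, 0.2),
                           cfg$n_probes, n_pat,
                           dimnames = list(probes, patients))

  # expression residual (log2 normalized, group x time centered) drives the
  # cis coupling
  sfac <- estimate_size_factors(counts)
  log_expr <- log2(sweep(counts, 2, sfac, "/") + 1)
  cond <- paste(rna_d$group, rna_d$timepoint)
  resid <- log_expr
  for (cc in unique(cond)) {
    j <- cond == cc
    resid[, j] <- log_expr[, j] - rowMeans(log_expr[, j, drop = FALSE])
  }
  resid_sd <- apply(resid, 1, stats::sd)
  zres <- resid / ifelse(resid_sd == 0, 1, resid_sd)
  rna_key <- paste(rna_d$patient_id, rna_d$timepoint)

  mval <- matrix(rep(base_m, n_meth), cfg$n_probes, n_meth,
                 dimnames = list(probes, meth_d$sample_id))
  # cis probes carry no independent patient effect: their between-patient
  # variation comes from the coupled gene, keeping the realized coupling at
  # the configured value
  patient_effect[match(cis_probes, probes), ] <- 0
  mval <- mval + patient_effect[, meth_d$patient_id]
  shifted <- matrix(FALSE, cfg$n_probes, n_meth, dimnames = dimnames(mval))
  shifted[persistent, ] <- shifted[persistent, ] |
    matrix(rep(meth_d$group == "remission" & meth_d$timepoint %in% c("2w", "6w"),
               each = length(persistent)), length(persistent), n_meth)
  shifted[transient, ] <- shifted[transient, ] |
    matrix(rep(meth_d$group == "non_remission" & meth_d$timepoint == "2w",
               each = length(transient)), length(transient), n_meth)
  shift_mat <- matrix(0, cfg$n_probes, n_meth, dimnames = dimnames(mval))
  shift_mat[dmp_probes, ] <- dmp_shift[dmp_probes] * shifted[dmp_probes, ]
  mval <- mval + shift_mat

  noise <- matrix(stats::rnorm(cfg$n_probes * n_meth, 0, cfg$beta_noise_sd),
                  cfg$n_probes, n_meth)
  # couple cis probes' noise to their gene's expression residual
  meth_key <- paste(meth_d$patient_id, meth_d$timepoint)
  col_match <- match(meth_key, rna_key)
  w <- cfg$cis_coupling
  for (i in seq_len(cfg$n_cis)) {
    p <- cis_probes[i]; g <- cis_genes[i]
    z <- zres[g, col_match]
    noise[match(p, probes), ] <- cfg$beta_noise_sd *
      (w * cis_sign[i] * z + sqrt(1 - w^2) * stats::rnorm(n_meth))
  }
  beta <- sigmoid(mval + noise)

  # probe annotation: cis probes sit within the TSS window of their gene;
  # a QC tail of flagged / sex-chromosome / missing probes exercises the
  # filter; everything else is placed uniformly
  probe_chrom <- sample(chroms, cfg$n_probes, replace = TRUE)
  max_pos <- max(annotation$tss) + 100000L
  probe_pos <- sample.int(max_pos, cfg$n_probes, replace = TRUE)
  gi <- match(cis_genes, annotation$gene_id)
  probe_chrom[match(cis_probes, probes)] <- annotation$chrom[gi]
  probe_pos[match(cis_probes, probes)] <- annotation$tss[gi] +
    sample(-4800:4800, cfg$n_cis, replace = TRUE)
  n_qc <- min(200L, cfg$n_probes - cfg$n_dmps)
  qc_probes <- utils::tail(probes, n_qc)
  flags <- data.frame(probe_id = probes,
                      chrom = probe_chrom, pos = probe_pos,
                      snp_overlap = FALSE, unreliable = FALSE,
                      context_specific = FALSE, stringsAsFactors = FALSE)
  if (n_qc >= 10) {
    grp <- rep_len(1:5, n_qc)
    flags$snp_overlap[match(qc_probes[grp == 1], probes)] <- TRUE
    flags$unreliable[match(qc_probes[grp == 2], probes)] <- TRUE
    flags$context_specific[match(qc_probes[grp == 3], probes)] <- TRUE
    flags$chrom[match(qc_probes[grp == 4], probes)] <- "chrX"
    beta[match(qc_probes[grp == 5], probes), 1] <- NA  # missing measurements
  }

  truth <- structure(list(
    seed = seed,
    config = unclass(cfg),
    genes = genes,
    probes = probes,
    de_genes = imp,
    deg_by_group = list(remission = remission_degs,
                        non_remission = non_remission_degs),
    module_membership = module_membership,
    disrupted_modules = data.frame(module = disrupted, group = "remission",
                                   timepoints = "2w,6w",
                                   stringsAsFactors = FALSE),
    planted_dmps = data.frame(
      probe_id = dmp_probes,
      group = ifelse(dmp_probes %in% persistent, "remission", "non_remission"),
      persistence = ifelse(dmp_probes %in% persistent, "persistent", "transient"),
      delta_beta = dmp_sign[dmp_probes] * cfg$dmp_delta_beta,
      stringsAsFactors = FALSE),
    cis_pairs = data.frame(probe_id = cis_probes, gene_id = cis_genes,
                           sign = cis_sign, stringsAsFactors = FALSE),
    predictive_features = predictive,
    loadings = loadings), class = "ground_truth")

  # clinical covariates: activity score tracks outcome over time, CRP loads on
  # module 1's factor, IL6 on module 2's; tryptophan and the cell counts are
  # noise
  act <- ifelse(design$group == "remission",
                ifelse(design$timepoint %in% c("2w", "6w", "14w"), 2, 7), 7)
  design$activity_score <- act + stats::rnorm(nrow(design), 0, 1)
  f_of <- function(m) {
    if (!m %in% rownames(factors)) return(numeric(nrow(design)))
    idx <- match(paste(design$patient_id, design$timepoint), rna_key)
    out <- factors[m, idx]
    out[is.na(out)] <- 0
    out
  }
  design$CRP <- 10 + 5 * f_of("M1") + stats::rnorm(nrow(design), 0, 2)
  design$IL6 <- 4 + 2 * f_of("M2") + stats::rnorm(nrow(design), 0, 1)
  design$tryptophan <- stats::rnorm(nrow(design), 60, 8)
  design$fecal_calprotectin <- exp(stats::rnorm(nrow(design), 5, 1))
  design$leukocytes <- stats::rnorm(nrow(design), 8, 2)

  structure(list(expr = expression_matrix(counts),
                 meth = methylation_matrix(beta, flags),
                 design = cohort_design(design),
                 annotation = annotation,
                 truth = truth),
            class = "sim_cohort")
}

#' Write a simulated cohort to the pipeline's file dialects
#'
#' Emits counts, betas + probe annotation, the design sheet, the gene BED6
#' annotation and a `ground_truth.json` manifest into a directory.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(cohort$expr, file.path(dir, "counts.tsv"))
  write_betas(cohort$meth, file.path(dir, "betas.tsv"),
              file.path(dir, "probe_annotation.tsv"))
  write_design(cohort$design, file.path(dir, "design.tsv"))
  write_tss(cohort$annotation, file.path(dir, "genes.bed"))
  truth <- unclass(cohort$truth)
  truth$module_membership <- as.list(truth$module_membership)
  truth$loadings <- as.list(truth$loadings)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
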