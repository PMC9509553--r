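test_that("BH adjustment equals the brute-force definition on short p-vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  withr::with_seed(7, {
    for (n in 1:6) for (rep in 1:30) {
      p <- round(runif(n), 3)
      expect_equal(p.adjust(p, "BH"), bh_oracle(p))
    }
  })
})

test_that("the impulse curve has the right constant, limit and step behavior", {
  t <- c(-1e6, 0, 24, 336, 1e6)
  expect_equal(impulse_value(t, 3, 3, 3, 10, 100, 0.1), rep(3, 5))
  f <- impulse_value(c(-1e5, 1e5), h0 = 2, h1 = 8, h2 = 5, t1 = 10, t2 = 100,
                     beta_slope = 0.05)
  expect_equal(f[1], 2, tolerance = 1e-6)   # t -> -Inf gives h0
  expect_equal(f[2], 5, tolerance = 1e-6)   # t -> +Inf gives h2
  # steep slopes give a step function equal to h1 between t1 and t2
  expect_equal(impulse_value(50, 2, 8, 5, 10, 100, beta_slope = 100), 8,
               tolerance = 1e-6)
  expect_error(impulse_value(1, -1, 2, 3, 0, 10, 1), "positive")
  expect_error(impulse_value(1, 1, 2, 3, 0, 10, -2), "positive")
})

make_paired_counts <- function(n_genes = 120, n_patients = 10, mu = 100,
                               size = 10, lfc_gene1 = 0, seed = 1) {
  withr::with_seed(seed, {
    tps <- c("baseline", "2w")
    design <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
      data.frame(sample_id = paste0("R_P", i, "_", tps),
                 patient_id = paste0("P", i), assay = "rna", timepoint = tps,
                 group = "remission", diagnosis = "CD", treatment = "anti_tnf")
    }))
    design <- cohort_design(design)
    mu_mat <- matrix(mu, n_genes, nrow(design))
    mu_mat[1:5, design$timepoint == "2w"] <- mu * 2^lfc_gene1
    counts <- named_counts(matrix(rnbinom(length(mu_mat), mu = mu_mat, size = size),
                                  n_genes, nrow(design)),
                           samples = design$sample_id)
    list(expr = normalize_counts(expression_matrix(counts)), design = design)
  })
}

test_that("pairwise DE recovers a planted 4-fold change with a sane estimate", {
  fx <- make_paired_counts(lfc_gene1 = 2, seed = 5)
  res <- pairwise_de(fx$expr, fx$design, "remission", "2w")
  planted <- res[res$gene_id %in% sprintf("g%02d", 1:5), ]
  expect_true(all(planted$fdr < 0.05))
  expect_gt(mean(planted$log2_fold_change), 1.6)
  expect_lt(mean(planted$log2_fold_change), 2.4)
  expect_true(all(planted$direction == "up"))
})

test_that("pairwise DE enforces pairing and logs all-zero genes", {
  fx <- make_paired_counts(n_patients = 2)
  expect_error(pairwise_de(fx$expr, fx$design, "remission", "2w"), ">= 3 patients")
  fx <- make_paired_counts(n_patients = 6, seed = 2)
  fx$expr$counts["g08", ] <- 0L
  fx$expr <- normalize_counts(expression_matrix(fx$expr$counts))
  res <- pairwise_de(fx$expr, fx$design, "remission", "2w")
  expect_false("g08" %in% res$gene_id)
  expect_true("g08" %in% attr(res, "excluded"))
})

test_that("longitudinal impulse DE finds a planted transient spike and places it in time", {
  n_pat <- 8; n_genes <- 60
  withr::with_seed(9, {
    design <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      data.frame(sample_id = paste0("R_P", i, "_", timepoint_levels()),
                 patient_id = paste0("P", i), assay = "rna",
                 timepoint = timepoint_levels(), group = "remission",
                 diagnosis = "CD", treatment = "anti_tnf")
    }))
    design <- cohort_design(design)
    mu_mat <- matrix(100, n_genes, nrow(design))
    spike <- design$timepoint %in% c("24h", "72h")
    mu_mat[1, spike] <- 800                      # 8-fold transient spike
    counts <- named_counts(matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 8),
                                  n_genes, nrow(design)),
                           samples = design$sample_id)
    expr <- normalize_counts(expression_matrix(counts))
  })
  res <- longitudinal_de(expr, design, "remission")
  g1 <- res[res$gene_id == "g01", ]
  expect_lt(g1$fdr, 0.05)
  expect_lt(g1$t1, 72)
  expect_gt(g1$t2, g1$t1)
  # fitted curve actually peaks inside the spike window
  fit48 <- impulse_value(48, g1$h0, g1$h1, g1$h2, g1$t1, g1$t2, g1$beta_slope)
  fit0 <- impulse_value(0, g1$h0, g1$h1, g1$h2, g1$t1, g1$t2, g1$beta_slope)
  expect_gt(fit48 / fit0, 2)
  expect_true(all(res$lrt_statistic >= 0, na.rm = TRUE))
})

test_that("longitudinal DE requires at least four timepoints", {
  fx <- make_paired_counts(n_patients = 6)
  expect_error(longitudinal_de(fx$expr, fx$design, "remission"), "4 distinct timepoints")
})

test_that("DEG set combination implements union and intersection with provenance", {
  pw <- list(data.frame(gene_id = c("A", "B", "C"),
                        contrast = "4h_vs_baseline.remission",
                        fdr = c(0.01, 0.02, 0.9)))
  lg <- data.frame(gene_id = c("A", "B", "C"), fdr = c(0.9, 0.01, 0.02))
  u <- combine_deg_sets(pw, lg, 0.05)
  expect_setequal(u$gene_id, c("A", "B", "C"))
  expect_equal(u$provenance[u$gene_id == "B"], "pairwise:4h;longitudinal")
  i <- combine_deg_sets(pw, lg, 0.05, mode = "intersection")
  expect_equal(i$gene_id, "B")
  empty <- combine_deg_sets(list(), data.frame(gene_id = character(0), fdr = numeric(0)), 0.05)
  expect_equal(nrow(empty), 0)

  p <- partition_deg_sets(c("A", "B", "C"), "B")
  expect_equal(p, list(remission_only = c("A", "C"), non_remission_only = character(0),
                       shared = "B"))
})

test_that("DEG cross-tabulation counts overlaps and labels directions", {
  a <- list(`up@4h` = c("g1", "g2"), `down@2w` = "g3")
  ident <- compare_deg_sets(a, a)
  expect_equal(unname(diag(ident$counts)), c(2L, 1L))
  disjoint <- compare_deg_sets(a, list(`up@4h` = "g9"))
  expect_true(all(disjoint$counts == 0))
  x <- compare_deg_sets(list(`up@4h` = "g1"), list(`down@2w` = "g1"))
  expect_equal(unname(x$counts[1, 1]), 1L)
  expect_equal(unname(x$direction[1, 1]), "opposite-direction")
})

test_that("the baseline contrast rejects group-diagnosis confounding", {
  fx <- make_paired_counts(n_patients = 8, seed = 3)
  d <- as.data.frame(fx$design)
  d$timepoint <- as.character(d$timepoint); d$hours <- NULL
  d$group <- ifelse(d$patient_id %in% paste0("P", 1:4), "remission", "non_remission")
  d$diagnosis <- ifelse(d$group == "remission", "CD", "UC")
  expect_error(baseline_contrast(fx$expr, cohort_design(d)), "confounded")
  d$diagnosis <- rep(c("CD", "UC"), length.out = nrow(d) / 2)[
    match(d$patient_id, unique(d$patient_id))]
  res <- baseline_contrast(fx$expr, cohort_design(d))
  expect_true(all(c("p_value", "fdr") %in% names(res)))
  d2 <- d[d$group == "remission", ]
  expect_error(baseline_contrast(fx$expr, cohort_design(d2)), "both outcome groups")
})

test_that("the PCA scan satisfies the partial-correlation identity and finds planted shifts", {
  n <- 40
  withr::with_seed(11, {
    groups <- rep(c("remission", "non_remission"), each = n / 2)
    design <- cohort_design(data.frame(
      sample_id = paste0("R_P", seq_len(n), "_baseline"),
      patient_id = paste0("P", seq_len(n)), assay = "rna",
      timepoint = "baseline", group = groups,
      diagnosis = rep(c("CD", "UC"), n / 2), treatment = "anti_tnf"))
    shift <- ifelse(groups == "remission", 1.5, 0)
    mu <- matrix(50, 60, n)
    mu[1:20, ] <- 50 * exp(rep(shift, each = 20))
    counts <- named_counts(matrix(rnbinom(length(mu), mu = mu, size = 20), 60, n),
                           samples = design$sample_id)
    expr <- normalize_counts(expression_matrix(counts))
  })
  scan <- pca_covariate_scan(expr, design, covariates = c("group", "diagnosis"))
  expect_true(max(abs(scan$correlations$rho[scan$correlations$covariate == "group"])) > 0.8)
  # scores are orthogonal with non-increasing explained variance
  cp <- crossprod(scan$scores)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))), tolerance = 1e-8)
  expect_true(all(diff(scan$explained) <= 1e-12))
  # partial correlation vanishes when r_xy = r_xz * r_yz
  expect_equal(tnfomics:::partial_cor(0.3 * 0.5, 0.3, 0.5), 0)
})
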