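test_that("cis window mapping is inclusive, strand-aware and symmetric", {
  ann <- gene_annotation(data.frame(
    gene_id = c("gP", "gM"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 50000L)))
  probes <- data.frame(
    probe_id = c("at_4999", "at_5001", "minus_3prime", "far"),
    chrom = "chr1",
    pos = c(14999L, 15001L, 53000L, 900000L))
  pairs <- map_cis_pairs(probes, c("gP", "gM"), ann, window_bp = 5000)
  expect_true("at_4999" %in% pairs$probe_id[pairs$gene_id == "gP"])
  expect_false("at_5001" %in% pairs$probe_id)
  # genomic-right of a minus-strand TSS is upstream: signed distance -3000
  expect_equal(pairs$signed_distance[pairs$probe_id == "minus_3prime"], -3000L)
  expect_false("far" %in% pairs$probe_id)

  # flipping the strand negates signed distances but keeps membership
  ann_flip <- ann; ann_flip$strand <- c("-", "+")
  pairs_flip <- map_cis_pairs(probes, c("gP", "gM"), ann_flip, window_bp = 5000)
  key <- function(p) sort(paste(p$probe_id, p$gene_id))
  expect_equal(key(pairs_flip), key(pairs))
  m <- merge(pairs, pairs_flip, by = c("probe_id", "gene_id"))
  expect_equal(m$signed_distance.x, -m$signed_distance.y)

  probes_other <- probes; probes_other$chrom <- "1"
  expect_error(map_cis_pairs(probes_other, c("gP", "gM"), ann, 5000),
               "chromosome")
})

test_that("Spearman correlation equals the rank-then-Pearson oracle exhaustively", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  x <- c(1, 2, 3, 4, 5)
  for (y in perms(c(1, 2, 2, 3, 4)))   # ties exercise average ranks
    expect_equal(cor(x, y, method = "spearman"), spearman_oracle(x, y))
  for (y in perms(c(2, 1, 3)))
    expect_equal(cor(c(1, 2, 3), y, method = "spearman"),
                 spearman_oracle(c(1, 2, 3), y))
})

test_that("pair correlation uses matched samples and flags degenerate probes", {
  fx <- cis_fixture(n_pairs = 10, n_coupled = 5, n_pat = 4)
  out <- correlate_pairs(fx$expr, fx$meth, fx$pairs, fx$design)
  expect_equal(out$n_samples[1], 12)          # 4 patients x 3 timepoints
  expect_true(all(abs(out$rho) <= 1, na.rm = TRUE))

  flat <- fx$meth$beta
  flat[1, ] <- 0.5
  meth_flat <- methylation_matrix(flat, fx$meth$annotation)
  expect_warning(out2 <- correlate_pairs(fx$expr, meth_flat, fx$pairs, fx$design),
                 "constant")
  expect_true(is.na(out2$rho[1]))

  d_small <- fx$design[fx$design$patient_id == "P01", ]
  expect_error(correlate_pairs(fx$expr, fx$meth, fx$pairs, d_small), ">= 4 matched")
})

test_that("a perfectly anticorrelated pair has rho -1 over matched samples", {
  fx <- cis_fixture(n_pairs = 6, n_coupled = 0, n_pat = 4)
  ms <- tnfomics:::matched_samples(fx$design)
  e <- fx$expr
  e$normalized[1, ms$rna_sample] <- seq_len(nrow(ms))
  b <- fx$meth$beta
  b[1, ms$meth_sample] <- seq(0.9, 0.1, length.out = nrow(ms))
  meth <- methylation_matrix(b, fx$meth$annotation)
  out <- correlate_pairs(e, meth, fx$pairs, fx$design)
  expect_equal(out$rho[1], -1)
})

test_that("permutation FDR recovers coupled pairs and never reports p = 0", {
  fx <- cis_fixture()
  pairs <- correlate_pairs(fx$expr, fx$meth, fx$pairs, fx$design)
  res <- permutation_fdr(pairs, fx$expr, fx$meth, fx$design,
                         n_permutations = 100, seed = 3)
  expect_true(all(res$empirical_p > 0))
  sig <- which(res$significant)
  expect_gte(length(intersect(sig, fx$coupled)) / length(fx$coupled), 0.7)
  # the most extreme pair attains the minimal possible empirical p
  strong <- which.max(abs(res$rho))
  n_null <- 100 * sum(!is.na(pairs$rho))
  expect_gte(res$empirical_p[strong], 1 / (1 + n_null))
  expect_error(permutation_fdr(pairs, fx$expr, fx$meth, fx$design,
                               n_permutations = 10, seed = 1), ">= 100")
  res2 <- permutation_fdr(pairs, fx$expr, fx$meth, fx$design,
                          n_permutations = 100, seed = 3)
  expect_identical(res, res2)
})

test_that("sign classification summarizes canonical negatives per pair and gene", {
  pairs <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g1", "g2"),
                      rho = c(-0.8, -0.5, 0.6),
                      significant = TRUE,
                      sign_class = c("canonical_negative", "canonical_negative",
                                     "positive"))
  s <- classify_signs(pairs)
  expect_equal(s$pairs$frac_negative, 2 / 3)
  expect_equal(s$genes$n_genes, 2)
  all_neg <- pairs; all_neg$rho <- -abs(all_neg$rho)
  all_neg$sign_class <- "canonical_negative"
  expect_equal(classify_signs(all_neg)$pairs$frac_negative, 1)
  none <- pairs; none$significant <- FALSE
  expect_error(classify_signs(none), "no significant")
})

test_that("module over-representation reproduces the 2x2 arithmetic", {
  membership <- setNames(c(rep("M1", 100), rep("M2", 200),
                           rep("unassigned", 700)), sprintf("g%04d", 1:1000))
  ms <- structure(list(membership = membership), class = "module_set")
  linked <- c(sprintf("g%04d", 1:40), sprintf("g%04d", 301:460))  # 40 in M1, 200 total
  tab <- module_overrepresentation(linked, ms)
  expect_equal(tab$ratio[tab$module == "M1"], 2.0)
  expect_equal(tab$expected[tab$module == "M1"], 20)
  unif <- withr::with_seed(2, sample(names(membership), 200))
  tab2 <- module_overrepresentation(unif, ms)
  expect_true(all(abs(tab2$ratio - 1) < 0.6))
})

test_that("replication concordance is exact on identical inputs and tracks sign flips", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:50),
                   contrast = "2w_vs_baseline.remission",
                   log2_fold_change = withr::with_seed(5, rnorm(50)))
  cis <- data.frame(probe_id = sprintf("p%02d", 1:20),
                    gene_id = sprintf("g%02d", 1:20),
                    rho = withr::with_seed(6, runif(20, -1, 1)))
  rep0 <- replication_concordance(de, de, cis, cis)
  expect_equal(rep0$lfc$rho, 1)
  expect_equal(rep0$cis$frac_sign_preserved, 1)
  cis_flip <- cis
  cis_flip$rho[1:2] <- -cis_flip$rho[1:2]     # 10% of pairs flipped
  rep1 <- replication_concordance(de, de, cis, cis_flip)
  expect_equal(rep1$cis$frac_sign_preserved, 0.9)
  de_b <- de; de_b$contrast <- "other"
  expect_error(replication_concordance(de, de_b), "share no contrasts")
})
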