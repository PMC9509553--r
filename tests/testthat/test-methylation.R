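make_meth <- function(beta, ann_over = list()) {
  n <- nrow(beta)
  ann <- data.frame(probe_id = rownames(beta),
                    chrom = "chr1", pos = seq_len(n) * 100L,
                    snp_overlap = FALSE, unreliable = FALSE,
                    context_specific = FALSE, stringsAsFactors = FALSE)
  for (nm in names(ann_over)) ann[[nm]] <- ann_over[[nm]]
  methylation_matrix(beta, ann)
}

test_that("probe filtering removes by ordered criteria and logs counts", {
  beta <- matrix(0.5, 10, 2, dimnames = list(sprintf("p%02d", 1:10), c("s1", "s2")))
  beta["p04", 1] <- NA
  meth <- make_meth(beta, list(
    snp_overlap = c(TRUE, TRUE, rep(FALSE, 8)),
    chrom = c(rep("chr1", 2), "chrX", rep("chr1", 7))))
  out <- filter_probes(meth)
  log <- attr(out, "filter_log")
  expect_equal(nrow(out$beta), 6)
  expect_equal(log$n, c(2, 0, 0, 1, 1, 6))

  clean <- filter_probes(make_meth(matrix(0.4, 5, 2,
    dimnames = list(paste0("q", 1:5), c("s1", "s2")))))
  expect_equal(nrow(clean$beta), 5)

  # a probe that is both SNP-flagged and on chrX is attributed to the SNP rule
  both <- make_meth(matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
                    list(snp_overlap = c(TRUE, FALSE), chrom = c("chrX", "chr1")))
  log2 <- attr(filter_probes(both), "filter_log")
  expect_equal(log2$n[log2$criterion == "snp_overlap"], 1)
  expect_equal(log2$n[log2$criterion == "sex_chromosome"], 0)
})

paired_meth_fixture <- function(n_probes = 400, n_pat = 12, delta = 0.2,
                                n_planted = 20, sd_logit = 0.3, seed = 21) {
  withr::with_seed(seed, {
    design <- tiny_design(n_pat, groups = rep("remission", n_pat))
    md <- design[design$assay == "methylation", ]
    base_m <- rnorm(n_probes, 0, 1)
    m <- matrix(base_m, n_probes, nrow(md)) +
      matrix(rnorm(n_probes * nrow(md), 0, sd_logit), n_probes)
    planted <- seq_len(n_planted)
    shift_cols <- md$timepoint %in% c("2w", "6w")
    for (p in planted) {
      b1 <- min(max(plogis(base_m[p]) + delta, 0.03), 0.97)
      m[p, shift_cols] <- m[p, shift_cols] + (qlogis(b1) - base_m[p])
    }
    beta <- plogis(m)
    dimnames(beta) <- list(sprintf("p%03d", seq_len(n_probes)), md$sample_id)
    list(meth = make_meth(beta), design = design,
         planted = sprintf("p%03d", planted))
  })
}

test_that("combined-rank DMP calling recovers planted shifts and honors its invariants", {
  fx <- paired_meth_fixture()
  dm <- dmp_combined_rank(fx$meth, fx$design, "remission", "2w")
  expect_equal(dm$combined_rank, pmax(dm$rank_diff, dm$rank_quot, dm$rank_p))
  expect_true(all(abs(dm$mean_diff) <= 1))
  expect_true(all(dm$direction == ifelse(dm$mean_diff >= 0, "hyper", "hypo")))
  planted <- dm[dm$probe_id %in% fx$planted, ]
  # the max-rank combination lets low-beta null probes outrank a few planted
  # probes on the quotient statistic, so recovery is high but not total
  expect_gte(mean(planted$combined_rank <= 0.05 * nrow(dm)), 0.8)
  expect_gte(mean(planted$significant), 0.8)
  expect_true(all(planted$p_value < 0.01))
})

test_that("combined ranks are permutation-equivariant and max-combined", {
  fx <- paired_meth_fixture(n_probes = 50, n_planted = 5)
  dm <- dmp_combined_rank(fx$meth, fx$design, "remission", "2w")
  perm <- withr::with_seed(3, sample(nrow(fx$meth$beta)))
  meth_p <- methylation_matrix(fx$meth$beta[perm, ],
                               fx$meth$annotation[perm, ])
  dm_p <- dmp_combined_rank(meth_p, fx$design, "remission", "2w")
  expect_equal(dm_p$combined_rank[match(dm$probe_id, dm_p$probe_id)],
               dm$combined_rank)
  # rank triple (5, 40, 12) combines to 40 under the max rule
  expect_equal(max(c(5, 40, 12)), 40)
  m <- fx$meth$beta
  d <- fx$design[fx$design$assay == "methylation", ]
  # a probe identical across states lands among the worst ranks
  flat <- m
  flat["p050", ] <- 0.5
  dmf <- dmp_combined_rank(make_meth(flat), fx$design, "remission", "2w")
  expect_equal(dmf$mean_diff[dmf$probe_id == "p050"], 0)
  expect_false(dmf$significant[dmf$probe_id == "p050"])
  expect_gt(dmf$rank_diff[dmf$probe_id == "p050"], nrow(flat) / 2)
})

test_that("DMP calling requires paired patients", {
  fx <- paired_meth_fixture(n_probes = 30, n_pat = 4)
  d <- fx$design[!(fx$design$patient_id %in% c("P01", "P02") &
                     fx$design$timepoint == "2w" &
                     fx$design$assay == "methylation"), ]
  expect_error(dmp_combined_rank(fx$meth, d, "remission", "2w"), "P01")
})

test_that("the automatic rank cutoff counts BH discoveries", {
  expect_equal(auto_rank_cutoff(data.frame(p_value = rep(1, 50))), 0)
  # null simulation: close to nothing called
  fx <- paired_meth_fixture(n_planted = 0, seed = 5)
  dm <- dmp_combined_rank(fx$meth, fx$design, "remission", "2w")
  expect_lte(attr(dm, "rank_cutoff"), 0.01 * nrow(dm))
  expect_lte(mean(dm$significant), 0.01)
  # 100 strong DMPs among 5000 probes put the cutoff near the planted count
  fx2 <- paired_meth_fixture(n_probes = 5000, n_planted = 100, delta = 0.3,
                             seed = 6)
  dm2 <- dmp_combined_rank(fx2$meth, fx2$design, "remission", "2w")
  expect_gte(attr(dm2, "rank_cutoff"), 80)
  expect_lte(attr(dm2, "rank_cutoff"), 150)
})

test_that("DMR aggregation scores regions by mean member rank", {
  fx <- paired_meth_fixture(n_probes = 200, n_planted = 10, delta = 0.3, seed = 8)
  dm <- dmp_combined_rank(fx$meth, fx$design, "remission", "2w")
  region_map <- rbind(
    data.frame(region_id = "prom1", region_class = "promoter",
               probe_id = fx$planted[1:5]),
    data.frame(region_id = "enh1", region_class = "enhancer",
               probe_id = c(fx$planted[6], sprintf("p%03d", 101:105))),
    data.frame(region_id = "cgi1", region_class = "cpg_island",
               probe_id = fx$planted[7]),
    data.frame(region_id = "gone", region_class = "gene",
               probe_id = "not_a_probe"))
  expect_warning(dmr <- dmr_aggregate(dm, region_map), NA)
  expect_true(dmr$significant[dmr$region_id == "prom1"])
  expect_false(dmr$significant[dmr$region_id == "enh1"])
  expect_true(dmr$single_probe[dmr$region_id == "cgi1"])
  expect_false(dmr$significant[dmr$region_id == "cgi1"])
  expect_false("gone" %in% dmr$region_id)
})

test_that("category representation tests give the expected ratios", {
  universe <- sprintf("p%04d", 1:2000)
  categories <- list(catA = universe[1:200])
  sig <- universe[1:40]                      # all significant probes in catA? no:
  sig <- c(universe[1:40], universe[301:460])  # 40 of 200 in catA, 200 total
  tab <- region_representation_test(sig, universe, categories)
  expect_equal(tab$ratio, 2.0)
  expect_equal(tab$observed, 40)
  expect_equal(tab$expected, 20)
  # uniform draws: ratios near 1 and the 0.05 test rejecting at ~5%
  hits <- withr::with_seed(4, vapply(1:10, function(i) {
    unif <- sample(universe, 200)
    t <- region_representation_test(unif, universe,
                                    list(catA = universe[1:500]))
    expect_lt(abs(t$ratio - 1), 0.35)
    t$p_value < 0.05
  }, logical(1)))
  expect_lte(sum(hits), 3)
  expect_warning(region_representation_test(sig, universe, list(none = character(0))),
                 "empty")
})
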