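test_that("signed adjacency maps correlations to [0,1] as specified", {
  expect_equal(signed_adjacency(matrix(c(1, 1, 1, 1), 2), 16)[1, 2], 1)
  expect_equal(signed_adjacency(matrix(c(1, -1, -1, 1), 2), 16)[1, 2], 0)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 16)[1, 2], 0.5^16)
  expect_error(signed_adjacency(matrix(c(1, 2, 2, 1), 2), 16), "\\[-1, 1\\]")
  # monotone in correlation
  a <- signed_adjacency(matrix(c(1, 0.2, 0.2, 1), 2), 6)[1, 2]
  b <- signed_adjacency(matrix(c(1, 0.6, 0.6, 1), 2), 6)[1, 2]
  expect_lt(a, b)
})

test_that("topological overlap matches the brute-force oracle on random networks", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      a <- matrix(runif(100), 10, 10)
      a <- (a + t(a)) / 2
      diag(a) <- 1
      tom <- tom_similarity(a)
      expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
      expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
      expect_equal(diag(tom), rep(1, 10))
    }
  })
})

test_that("module detection recovers orthogonal latent blocks exactly", {
  x <- block_expression(n_per_block = 50, n_samples = 30, noise_sd = 0.2)
  ms <- detect_modules(x, power = 6, min_module_size = 15)
  truth <- rep(c("A", "B"), each = 50)
  expect_equal(length(setdiff(unique(ms$membership), "unassigned")), 2)
  expect_equal(adjusted_rand_index(ms$membership, truth), 1)
})

test_that("module detection leaves i.i.d. noise genes unassigned", {
  x <- withr::with_seed(4, matrix(rnorm(200 * 30), 200, 30,
                                  dimnames = list(sprintf("g%03d", 1:200),
                                                  sprintf("s%03d", 1:30))))
  ms <- detect_modules(x, power = 6, min_module_size = 15)
  expect_gte(mean(ms$membership == "unassigned"), 0.9)
})

test_that("too few genes gives an all-unassigned module set with a warning", {
  x <- block_expression(n_per_block = 5, n_samples = 20)
  expect_warning(ms <- detect_modules(x, 6, min_module_size = 15), "unassigned")
  expect_true(all(ms$membership == "unassigned"))
})

test_that("module detection is invariant to gene and sample ordering", {
  x <- block_expression(n_per_block = 30, n_noise = 20, n_samples = 30, seed = 8)
  ms1 <- detect_modules(x, 6, min_module_size = 15)
  perm_g <- withr::with_seed(1, sample(nrow(x)))
  perm_s <- withr::with_seed(2, sample(ncol(x)))
  ms2 <- detect_modules(x[perm_g, perm_s], 6, min_module_size = 15)
  common <- rownames(x)
  expect_equal(adjusted_rand_index(ms1$membership[common], ms2$membership[common]), 1)
})

test_that("soft-threshold selection honors the target and falls back on noise", {
  # hub-structured modular data: heavy-tailed loadings over a noise background
  # give a connectivity distribution whose decay is scale-free at high powers
  x <- withr::with_seed(12, {
    n_s <- 80
    f <- matrix(rnorm(6 * n_s), 6, n_s)
    blocks <- lapply(1:6, function(m) {
      l <- runif(50)^2 * 2.8 + 0.2
      t(sapply(seq_along(l), function(i) l[i] * f[m, ] + rnorm(n_s)))
    })
    x <- rbind(do.call(rbind, blocks), matrix(rnorm(200 * n_s), 200, n_s))
    dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                        sprintf("s%03d", seq_len(n_s)))
    x
  })
  p <- pick_soft_threshold(x, power_grid = c(1:10, 12, 14, 16, 18, 20),
                           target_r2 = 0.8)
  expect_true(attr(p, "target_reached"))
  ft <- attr(p, "fit_table")
  expect_gt(ft$fit[ft$power == as.integer(p)], 0.8)
  expect_true(all(ft$fit[ft$power < as.integer(p)] <= 0.8))

  noise <- withr::with_seed(13, matrix(rnorm(200 * 20), 200, 20,
                                       dimnames = list(sprintf("g%03d", 1:200),
                                                       sprintf("s%03d", 1:20))))
  expect_warning(pn <- pick_soft_threshold(noise, target_r2 = 0.99), "no power")
  expect_false(attr(pn, "target_reached"))
  ft <- attr(pn, "fit_table")
  expect_equal(as.integer(pn), ft$power[which.max(ft$fit)])
  expect_error(pick_soft_threshold(noise, power_grid = integer(0)), "empty")
})

test_that("close modules merge iteratively on eigengene dissimilarity", {
  # two planted factors with correlation ~0.9 -> eigengene dissimilarity < 0.2
  mk <- function(rho, seed = 5) withr::with_seed(seed, {
    n_s <- 60
    f1 <- rnorm(n_s)
    f2 <- rho * f1 + sqrt(1 - rho^2) * rnorm(n_s)
    x <- rbind(t(sapply(1:30, function(i) f1 + rnorm(n_s, 0, 0.3))),
               t(sapply(1:30, function(i) f2 + rnorm(n_s, 0, 0.3))))
    dimnames(x) <- list(sprintf("g%03d", 1:60), sprintf("s%03d", 1:n_s))
    x
  })
  x <- mk(0.95)
  membership <- setNames(rep(c("M1", "M2"), each = 30), rownames(x))
  ms <- module_eigengenes_and_kme(x, membership)
  merged <- merge_close_modules(ms, x, cut_height = 0.2)
  expect_equal(length(setdiff(unique(merged$membership), "unassigned")), 1)

  x2 <- mk(0.5)
  ms2 <- module_eigengenes_and_kme(x2, setNames(rep(c("M1", "M2"), each = 30),
                                                rownames(x2)))
  merged2 <- merge_close_modules(ms2, x2, cut_height = 0.2)
  expect_equal(length(setdiff(unique(merged2$membership), "unassigned")), 2)

  one <- module_eigengenes_and_kme(x, setNames(rep("M1", 60), rownames(x)))
  same <- merge_close_modules(one, x, 0.2)
  expect_equal(length(setdiff(unique(same$membership), "unassigned")), 1)
})

test_that("eigengenes summarize modules and kME measures membership", {
  n_s <- 20
  prof <- withr::with_seed(6, rnorm(n_s))
  x <- rbind(g1 = 2 * prof + 5, g2 = -1 * (2 * prof + 5) + 40, g3 = prof)
  x <- rbind(x, g4 = withr::with_seed(7, rnorm(n_s)))
  colnames(x) <- sprintf("s%02d", 1:n_s)
  ms <- module_eigengenes_and_kme(x, setNames(c("M1", "M1", "M1", "M1")[1:3],
                                              c("g1", "g2", "g3")))
  expect_equal(unname(sd(ms$eigengenes["M1", ])), 1)
  # identical (up to affine sign) profiles: |kME| = 1
  expect_equal(abs(unname(ms$kme["g1", "M1"])), 1, tolerance = 1e-8)

  x5 <- block_expression(n_per_block = 40, n_samples = 200, loading = 0.8,
                         noise_sd = sqrt(1 - 0.8^2), seed = 10)
  ms5 <- module_eigengenes_and_kme(x5, setNames(rep(c("M1", "M2"), each = 40),
                                                rownames(x5)))
  mean_kme <- mean(diag(ms5$kme[1:40, rep("M1", 40)]))
  expect_gt(mean_kme, 0.7)
  expect_lt(mean_kme, 0.9)
})

test_that("module-trait correlation is a rank statistic with significance stars", {
  x <- block_expression(n_per_block = 20, n_samples = 14, seed = 3)
  design <- tiny_design(2)
  smp <- design$sample_id[design$assay == "rna"]
  colnames(x) <- smp
  ms <- module_eigengenes_and_kme(x, setNames(rep(c("M1", "M2"), each = 20),
                                              rownames(x)))
  d2 <- design
  d2$cov_up <- NA_real_
  d2$cov_down <- NA_real_
  d2$cov_up[match(smp, d2$sample_id)] <- rank(ms$eigengenes["M1", ])
  d2$cov_down[match(smp, d2$sample_id)] <- -exp(ms$eigengenes["M1", ])
  tab <- module_trait_correlation(ms$eigengenes, d2, c("cov_up", "cov_down"))
  expect_equal(tab$rho[tab$module == "M1" & tab$covariate == "cov_up"], 1)
  expect_equal(tab$rho[tab$module == "M1" & tab$covariate == "cov_down"], -1)
  expect_equal(tab$stars[tab$module == "M1" & tab$covariate == "cov_up"], "***")
})
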