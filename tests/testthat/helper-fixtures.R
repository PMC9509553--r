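# Shared fixtures: tiny cohort configurations and hand-built matrices.

# A small but complete cohort: fast enough for unit tests, large enough that
# every stage has something to find.
small_sim <- function(...) {
  defaults <- list(n_per_group = 6, n_genes = 150, n_probes = 300,
                   n_modules = 2, module_size = 25, n_disrupted = 1,
                   n_de = 60, n_de_remission_specific = 50,
                   n_dmps = 60, n_cis = 20, n_cis_negative = 13,
                   n_predictive = 5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Minimal valid design: n patients, both assays, all timepoints.
tiny_design <- function(n_patients = 4, groups = NULL) {
  patients <- sprintf("P%02d", seq_len(n_patients))
  if (is.null(groups))
    groups <- rep(c("remission", "non_remission"), length.out = n_patients)
  rows <- list()
  for (i in seq_along(patients)) {
    for (tp in timepoint_levels())
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0("R_", patients[i], "_", tp),
        patient_id = patients[i], assay = "rna", timepoint = tp,
        group = groups[i], diagnosis = c("CD", "UC")[1 + i %% 2],
        treatment = "anti_tnf", stringsAsFactors = FALSE)
    for (tp in methylation_timepoints())
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0("M_", patients[i], "_", tp),
        patient_id = patients[i], assay = "methylation", timepoint = tp,
        group = groups[i], diagnosis = c("CD", "UC")[1 + i %% 2],
        treatment = "anti_tnf", stringsAsFactors = FALSE)
  }
  cohort_design(do.call(rbind, rows))
}

# Counts matrix with named dimensions.
named_counts <- function(m, genes = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Expression with two planted orthogonal latent blocks plus background genes.
block_expression <- function(n_per_block = 50, n_noise = 0, n_samples = 30,
                             loading = 1, noise_sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
    x <- rbind(
      t(sapply(seq_len(n_per_block), function(i) loading * f1 + rnorm(n_samples, 0, noise_sd))),
      t(sapply(seq_len(n_per_block), function(i) loading * f2 + rnorm(n_samples, 0, noise_sd))))
    if (n_noise > 0)
      x <- rbind(x, matrix(rnorm(n_noise * n_samples), n_noise, n_samples))
    rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%03d", seq_len(n_samples))
    x
  })
}

# Brute-force Benjamini-Hochberg, straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  for (i in seq_len(n))
    adj[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force topological overlap from its definition.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  t_mat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { t_mat[i, j] <- 1; next }
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    t_mat[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t_mat
}

# Brute-force Clopper-Pearson interval by inverting exact binomial tests over
# a fine grid.
clopper_pearson_oracle <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  grid <- seq(0, 1, by = 1e-5)
  lower_ok <- vapply(grid, function(p) pbinom(x - 1, n, p, lower.tail = FALSE) >= alpha / 2,
                     logical(1))
  upper_ok <- vapply(grid, function(p) pbinom(x, n, p) >= alpha / 2, logical(1))
  c(if (x == 0) 0 else min(grid[lower_ok]),
    if (x == n) 1 else max(grid[upper_ok]))
}

# Spearman by definition: Pearson on average ranks.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Cis-pair fixture: matched two-layer cohort with optionally coupled pairs.
cis_fixture <- function(n_pairs = 60, n_coupled = 20, coupling = 0.8,
                        n_pat = 12, seed = 31, negative_frac = 0.65) {
  withr::with_seed(seed, {
    design <- tiny_design(n_pat)
    rd <- design[design$assay == "rna", ]
    md <- design[design$assay == "methylation", ]
    n_genes <- n_pairs
    counts <- named_counts(matrix(rnbinom(n_genes * nrow(rd), mu = 200, size = 8),
                                  n_genes, nrow(rd)),
                           genes = sprintf("g%03d", 1:n_genes),
                           samples = rd$sample_id)
    expr <- normalize_counts(expression_matrix(counts))
    lx <- log2(expr$normalized + 1)
    z <- t(scale(t(lx)))
    key_r <- paste(rd$patient_id, rd$timepoint)
    key_m <- paste(md$patient_id, md$timepoint)
    idx <- match(key_m, key_r)
    sgn <- ifelse(seq_len(n_pairs) <= round(negative_frac * n_coupled) &
                    seq_len(n_pairs) <= n_coupled, -1, 1)
    m <- matrix(rnorm(n_pairs * nrow(md), 0, 0.3), n_pairs)
    for (i in seq_len(n_coupled))
      m[i, ] <- 0.3 * (coupling * sgn[i] * z[i, idx] +
                         sqrt(1 - coupling^2) * rnorm(nrow(md)))
    beta <- plogis(m)
    dimnames(beta) <- list(sprintf("p%03d", 1:n_pairs), md$sample_id)
    ann <- data.frame(probe_id = rownames(beta), chrom = "chr1",
                      pos = 1:n_pairs * 100L,
                      snp_overlap = FALSE, unreliable = FALSE,
                      context_specific = FALSE)
    pairs <- data.frame(probe_id = rownames(beta),
                        gene_id = sprintf("g%03d", 1:n_pairs),
                        signed_distance = 0L)
    list(expr = expr, meth = methylation_matrix(beta, ann), design = design,
         pairs = pairs, coupled = seq_len(n_coupled), sign = sgn)
  })
}

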