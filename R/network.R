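# Signed weighted co-expression network: soft thresholding, topological
# overlap, module detection by an adaptive tree cut, module merging,
# eigengenes, kME and module-trait correlation.

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power`: negative correlations map toward 0
#' instead of being folded onto positive ones.
#'
#' @param correlations symmetric gene-gene correlation matrix with unit
#'   diagonal.
#' @param power soft-threshold power (beta).
#' @return Adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(correlations, power) {
  if (any(abs(correlations) > 1 + 1e-8))
    stop_tnf("correlations must lie in [-1, 1]")
  a <- ((1 + pmin(pmax(correlations, -1), 1)) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` is the connectivity of
#' node i (sum of its adjacencies excluding itself). `TOM_ii = 1`.
#'
#' @param adjacency adjacency matrix in \[0, 1\], unit diagonal.
#' @return TOM similarity matrix in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

# Gene-gene Pearson correlation on the network working scale (rows = genes).
network_correlation <- function(expr_log) {
  stats::cor(t(expr_log))
}

# Scale-free topology fit: R^2 of log10 frequency vs log10 connectivity over
# equal-width connectivity bins, signed so that the scale-free direction
# (frequency decaying with connectivity, negative slope) scores positive.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mids <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mids[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Choose the soft-threshold power for a signed network
#'
#' Returns the minimum power on the grid whose scale-free topology fit exceeds
#' the target (0.9 in the discovery analysis, attained at power 16 there). If
#' no power reaches the target, returns the power with the best fit, with
#' attribute `target_reached = FALSE` and a warning.
#'
#' @param expr_log log2(x + 1) normalized expression, genes x samples.
#' @param power_grid candidate integer powers.
#' @param target_r2 required signed scale-free fit.
#' @return Integer power with attributes `fit_table` and `target_reached`.
#' @export
pick_soft_threshold <- function(expr_log, power_grid = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.9) {
  if (length(power_grid) == 0) stop_tnf("power grid is empty")
  sds <- apply(expr_log, 1, stats::sd)
  if (all(sds == 0)) stop_tnf("all genes have zero variance")
  cors <- network_correlation(expr_log[sds > 0, , drop = FALSE])
  fits <- vapply(power_grid, function(p) {
    a <- signed_adjacency(cors, p)
    scale_free_fit(rowSums(a) - 1)
  }, numeric(1))
  tab <- data.frame(power = power_grid, fit = fits)
  hit <- which(fits > target_r2)
  if (length(hit) > 0) {
    power <- power_grid[min(hit)]
    reached <- TRUE
  } else {
    power <- power_grid[which.max(fits)]
    reached <- FALSE
    warning(sprintf("no power reached scale-free fit %.2f; using %d (fit %.2f)",
                    target_r2, power, max(fits)))
  }
  structure(as.integer(power), fit_table = tab, target_reached = reached)
}

# Adaptive branch cut: scans a descending ladder of merge-height quantiles,
# cuts the average-linkage tree at each, and keeps the cut that yields the
# most valid clusters. A cluster is valid when it has >= min_module_size
# members and its mean within-cluster correlation clears `min_module_cor`
# (a power-independent coherence floor, so pure-noise branches never become
# modules). Ties prefer the higher cut (maximal clusters); over-split modules
# are healed downstream by eigengene merging. Deterministic; simpler than the
# published hybrid dynamic cut.
adaptive_tree_cut <- function(dist_mat, min_module_size, cor_mat = NULL,
                              cut_quantiles = seq(0.5, 0.995, by = 0.015),
                              min_module_cor = 0.2) {
  n <- nrow(dist_mat)
  genes <- rownames(dist_mat)
  if (is.null(cor_mat)) cor_mat <- 1 - dist_mat
  tree <- stats::hclust(stats::as.dist(dist_mat), method = "average")

  mean_off <- function(m) mean(m[upper.tri(m)])
  valid_clusters <- function(h) {
    labels <- stats::cutree(tree, h = h)
    cl <- split(genes, labels)
    cl <- cl[lengths(cl) >= min_module_size]
    cl[vapply(cl, function(g)
      mean_off(cor_mat[g, g, drop = FALSE]) > min_module_cor, logical(1))]
  }
  heights <- unique(stats::quantile(tree$height, sort(cut_quantiles,
                                                      decreasing = TRUE),
                                    names = FALSE))
  best <- list(); best_n <- -1L
  for (h in heights) {
    cl <- valid_clusters(h)
    if (length(cl) > best_n) { best <- cl; best_n <- length(cl) }
  }
  membership <- stats::setNames(rep("unassigned", n), genes)
  if (length(best) > 0) {
    ord <- order(-lengths(best),
                 vapply(best, function(cl) min(match(cl, genes)), numeric(1)))
    for (i in seq_along(ord))
      membership[best[[ord[i]]]] <- paste0("M", i)
  }
  membership
}

#' Detect co-expression modules
#'
#' Builds the signed adjacency at the given power from gene-gene Pearson
#' correlations of `expr_log`, converts it to a topological-overlap
#' dissimilarity (or `1 - adjacency` when `tree_distance = "adjacency"`),
#' clusters genes by average linkage, and cuts the tree with a deterministic
#' adaptive branch cut (height-ladder search; see details in the package
#' vignette). Clusters smaller than `min_module_size`, or whose mean
#' within-cluster correlation does not clear `min_module_cor`, are labeled
#' `"unassigned"`. Modules are named M1, M2, ... by decreasing size.
#'
#' @param expr_log log2(x + 1) normalized expression, genes x samples.
#' @param power soft-threshold power.
#' @param min_module_size smallest named module.
#' @param tree_distance `"tom"` or `"adjacency"`.
#' @param min_module_cor coherence floor: minimum mean within-module Pearson
#'   correlation for a cluster to become a named module.
#' @param kme_floor minimum module membership (correlation with the module's
#'   own eigengene) for a gene to stay in its module.
#' @return An object of class `module_set`: list with `membership` (named
#'   character vector), `power`, `eigengenes`, `kme` (both filled by
#'   [module_eigengenes_and_kme()]).
#' @export
detect_modules <- function(expr_log, power, min_module_size = 15,
                           tree_distance = c("tom", "adjacency"),
                           min_module_cor = 0.2, kme_floor = 0.45) {
  tree_distance <- match.arg(tree_distance)
  genes <- rownames(expr_log)
  if (nrow(expr_log) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    ms <- structure(list(membership = stats::setNames(
      rep("unassigned", nrow(expr_log)), genes),
      power = power, eigengenes = NULL, kme = NULL), class = "module_set")
    return(ms)
  }
  cors <- network_correlation(expr_log)
  adj <- signed_adjacency(cors, power)
  dm <- if (tree_distance == "tom") 1 - tom_similarity(adj) else 1 - adj
  dimnames(dm) <- list(genes, genes)
  membership <- adaptive_tree_cut(dm, min_module_size, cor_mat = cors,
                                  min_module_cor = min_module_cor)
  # kME refinement: tree branches absorb weakly correlated hangers-on, so
  # drop members whose correlation with their own module eigengene falls
  # below kme_floor, recomputing eigengenes in between
  for (it in 1:2) {
    if (all(membership == "unassigned")) break
    ms <- module_eigengenes_and_kme(expr_log, membership)
    for (g in names(membership)) {
      m <- membership[g]
      if (m != "unassigned" && !is.na(ms$kme[g, m]) && ms$kme[g, m] < kme_floor)
        membership[g] <- "unassigned"
    }
    sizes <- table(membership)
    too_small <- names(sizes)[sizes < min_module_size & names(sizes) != "unassigned"]
    membership[membership %in% too_small] <- "unassigned"
  }
  ms <- structure(list(membership = membership, power = power,
                       eigengenes = NULL, kme = NULL), class = "module_set")
  module_eigengenes_and_kme(expr_log, ms)
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$membership)
  cat(sprintf("module_set: %d genes, %d modules (power %s)\n",
              length(x$membership), sum(names(tab) != "unassigned"), x$power))
  print(tab)
  invisible(x)
}

#' Module eigengenes and module membership (kME)
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression, scaled to unit variance across samples and
#' sign-oriented so that its correlation with the module's mean standardized
#' expression is positive. `kME[g, m]` is the Pearson correlation between gene
#' g's expression and module m's eigengene.
#'
#' @param expr_log expression matrix, genes x samples.
#' @param modules a `module_set` (or named membership vector).
#' @return The `module_set` with `eigengenes` (modules x samples) and `kme`
#'   (genes x modules) filled.
#' @export
module_eigengenes_and_kme <- function(expr_log, modules) {
  membership <- if (inherits(modules, "module_set")) modules$membership else modules
  mods <- setdiff(sort(unique(membership)), "unassigned")
  mods <- mods[order(as.numeric(sub("^M", "", mods)))]
  if (length(mods) == 0) {
    if (inherits(modules, "module_set")) {
      modules$eigengenes <- NULL; modules$kme <- NULL
      return(modules)
    }
    return(structure(list(membership = membership, power = NA,
                          eigengenes = NULL, kme = NULL), class = "module_set"))
  }
  eg <- matrix(NA_real_, length(mods), ncol(expr_log),
               dimnames = list(mods, colnames(expr_log)))
  for (m in mods) {
    genes <- names(membership)[membership == m]
    x <- expr_log[genes, , drop = FALSE]
    xs <- t(scale(t(x)))                       # standardize each gene
    xs[is.na(xs)] <- 0                         # zero-variance genes
    if (length(genes) == 1) {
      e <- xs[1, ]
    } else {
      sv <- svd(t(xs), nu = 1, nv = 0)
      e <- sv$u[, 1]
    }
    if (stats::sd(e) > 0) e <- e / stats::sd(e)
    mean_prof <- colMeans(xs)
    if (stats::cor(e, mean_prof) < 0) e <- -e
    eg[m, ] <- e
  }
  kme <- stats::cor(t(expr_log), t(eg))        # genes x modules
  colnames(kme) <- mods
  if (!inherits(modules, "module_set"))
    modules <- structure(list(membership = membership, power = NA,
                              eigengenes = NULL, kme = NULL),
                         class = "module_set")
  modules$eigengenes <- eg
  modules$kme <- kme
  modules
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest module pair whose eigengene dissimilarity
#' (1 - Pearson correlation of eigengenes) is below `cut_height`, recomputing
#' eigengenes after every merge, until no pair qualifies. Merged modules are
#' relabeled M1, M2, ... by decreasing size.
#'
#' @param modules a `module_set` with eigengenes.
#' @param expr_log the expression matrix the modules were built on.
#' @param cut_height dissimilarity threshold (0.2 in the discovery analysis).
#' @return The merged `module_set`.
#' @export
merge_close_modules <- function(modules, expr_log, cut_height = 0.2) {
  membership <- modules$membership
  repeat {
    ms <- module_eigengenes_and_kme(expr_log, membership)
    mods <- rownames(ms$eigengenes)
    if (is.null(mods) || length(mods) < 2) break
    dis <- 1 - stats::cor(t(ms$eigengenes))
    diag(dis) <- Inf
    if (min(dis) >= cut_height) break
    idx <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    keep <- mods[min(idx)]; drop <- mods[max(idx)]
    membership[membership == drop] <- keep
  }
  # relabel by size, descending; stable tie-break by first gene position
  mods <- setdiff(unique(membership), "unassigned")
  sizes <- vapply(mods, function(m) sum(membership == m), numeric(1))
  firsts <- vapply(mods, function(m) min(which(membership == m)), numeric(1))
  ord <- mods[order(-sizes, firsts)]
  relabeled <- membership
  for (i in seq_along(ord))
    relabeled[membership == ord[i]] <- paste0("M", i)
  out <- module_eigengenes_and_kme(expr_log, relabeled)
  out$power <- modules$power
  out
}

#' Spearman correlation of module eigengenes with clinical covariates
#'
#' @param eigengenes modules x samples matrix.
#' @param design a [cohort_design()] covering the samples.
#' @param covariates design columns (numeric, or factors rank-coded).
#' @return data.frame: module, covariate, rho, p_value, stars (`*` < 0.05,
#'   `**` < 0.01, `***` < 0.001), n (complete cases).
#' @export
module_trait_correlation <- function(eigengenes, design, covariates) {
  d <- design[match(colnames(eigengenes), design$sample_id), , drop = FALSE]
  rows <- list()
  for (m in rownames(eigengenes)) for (cv in covariates) {
    v <- d[[cv]]
    if (is.null(v)) stop_tnf("covariate '%s' not found in design", cv)
    if (!is.numeric(v)) v <- as.numeric(factor(v))
    ok <- !is.na(v)
    if (sum(ok) < 4 || length(unique(v[ok])) < 2) {
      warning(sprintf("covariate '%s' has < 4 complete cases or is constant", cv))
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(eigengenes[m, ok], v[ok],
                                             method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    stars <- if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
             else if (p < 0.05) "*" else ""
    rows[[length(rows) + 1]] <- data.frame(
      module = m, covariate = cv, rho = rho, p_value = p, stars = stars,
      n = sum(ok), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
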