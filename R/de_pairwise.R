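# Pairwise (timepoint vs baseline) differential expression: per-gene negative
# binomial GLM with size-factor offsets, patient blocking, moment dispersion
# shrunk toward a mean-dispersion trend, Wald test.

# Gene-wise moment dispersion: for each gene, pool the within-condition method
# of moments estimate alpha = (var - mean)/mean^2 on normalized counts, then
# shrink 50/50 toward a log-linear mean-dispersion trend fitted across genes.
moment_dispersions <- function(norm_counts, condition, shrink_weight = 0.5,
                               floor = 1e-4, ceiling = 10) {
  condition <- as.factor(condition)
  mu <- rowMeans(norm_counts)
  raw <- vapply(seq_len(nrow(norm_counts)), function(g) {
    x <- norm_counts[g, ]
    num <- 0; den <- 0
    for (lev in levels(condition)) {
      xi <- x[condition == lev]
      if (length(xi) >= 2 && mean(xi) > 0) {
        num <- num + (stats::var(xi) - mean(xi)) * (length(xi) - 1)
        den <- den + mean(xi)^2 * (length(xi) - 1)
      }
    }
    if (den == 0) return(NA_real_)
    num / den
  }, numeric(1))
  raw <- pmin(pmax(raw, floor), ceiling)
  ok <- !is.na(raw) & mu > 0
  trend <- rep(stats::median(raw[ok]), length(raw))
  if (sum(ok) >= 10) {
    fit <- stats::lm(log(raw[ok]) ~ log(mu[ok]))
    trend[ok] <- exp(stats::predict(fit))
    trend[!ok] <- exp(mean(log(raw[ok])))
  }
  alpha <- (1 - shrink_weight) * raw + shrink_weight * trend
  alpha[is.na(alpha)] <- trend[is.na(alpha)]
  pmin(pmax(alpha, floor), ceiling)
}

# Wald test on one coefficient of a fixed-dispersion NB GLM. The log size
# factors enter as an `off` column referenced by `offset(off)` in the formula.
nb_wald <- function(y, design_df, formula, coef_name, offset, alpha) {
  dat <- cbind(design_df, y = y, off = offset)
  form <- stats::update(formula, . ~ . + offset(off))
  environment(form) <- environment()
  fit <- tryCatch(
    suppressWarnings(stats::glm(form, data = dat,
                                family = MASS::negative.binomial(theta = 1 / alpha))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA, NA, NA, NA))
  sm <- summary(fit)$coefficients
  if (!coef_name %in% rownames(sm)) return(c(NA, NA, NA, NA))
  est <- sm[coef_name, "Estimate"]
  se <- sm[coef_name, "Std. Error"]
  z <- est / se
  # t reference with residual df: the patient blocking factor consumes much
  # of the sample size, so a normal reference is anticonservative at n ~ 10
  df_res <- max(1, length(y) - nrow(sm))
  c(est, se, z, 2 * stats::pt(-abs(z), df = df_res))
}

#' Pairwise differential expression: one timepoint versus baseline
#'
#' Fits, per gene, a negative binomial GLM with log link, log size factors as
#' offset, a patient blocking factor and a timepoint factor, within one outcome
#' group. Dispersion is a gene-wise moment estimate shrunk 50/50 toward a
#' log-linear mean-dispersion trend. The timepoint coefficient is tested by a
#' Wald test; p-values are Benjamini-Hochberg adjusted over the tested genes.
#' Genes with zero counts in every used sample are excluded and listed in the
#' `excluded` attribute of the result.
#'
#' @param expr a normalized [expression_matrix()].
#' @param design a [cohort_design()].
#' @param group outcome group, `"remission"` or `"non_remission"`.
#' @param timepoint test timepoint label (e.g. `"2w"`).
#' @param covariates optional design column names added to the model.
#' @param shrink_weight weight of the trend in dispersion shrinkage.
#' @return data.frame with columns `gene_id`, `contrast`, `log2_fold_change`,
#'   `standard_error`, `statistic`, `p_value`, `fdr`, `direction`.
#' @export
pairwise_de <- function(expr, design, group, timepoint, covariates = NULL,
                        shrink_weight = 0.5) {
  d <- design_subset(design, assay = "rna", group = group,
                     timepoints = c("baseline", timepoint))
  tab <- table(d$patient_id)
  complete <- names(tab)[tab == 2]
  if (length(complete) < 3)
    stop_tnf("pairwise DE needs >= 3 patients with both baseline and %s samples (have %d)",
             timepoint, length(complete))
  d <- d[d$patient_id %in% complete, , drop = FALSE]
  d <- d[order(d$patient_id, d$timepoint), , drop = FALSE]
  if (is.null(expr$size_factors)) expr <- normalize_counts(expr)
  counts <- expr$counts[, d$sample_id, drop = FALSE]
  sf <- expr$size_factors[d$sample_id]
  keep <- rowSums(counts) > 0
  excluded <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]

  dd <- data.frame(patient = factor(d$patient_id),
                   tp = factor(as.character(d$timepoint),
                               levels = c("baseline", timepoint)))
  form <- y ~ patient + tp
  if (!is.null(covariates)) {
    for (cv in covariates) dd[[cv]] <- d[[cv]]
    form <- stats::as.formula(paste("y ~ patient + tp +",
                                    paste(covariates, collapse = " + ")))
  }
  mm <- stats::model.matrix(form[-2], dd)
  if (qr(mm)$rank < ncol(mm))
    stop_tnf("singular design: confounded factors among %s",
             paste(colnames(dd), collapse = ", "))

  alpha <- moment_dispersions(sweep(counts, 2, sf, "/"), dd$tp,
                              shrink_weight = shrink_weight)
  coef_name <- paste0("tp", timepoint)
  res <- t(vapply(seq_len(nrow(counts)), function(g)
    nb_wald(counts[g, ], dd, form, coef_name, log(sf), alpha[g]),
    numeric(4)))
  out <- data.frame(
    gene_id = rownames(counts),
    contrast = sprintf("%s_vs_baseline.%s", timepoint, group),
    log2_fold_change = res[, 1] / log(2),
    standard_error = res[, 2] / log(2),
    statistic = res[, 3],
    p_value = res[, 4],
    stringsAsFactors = FALSE
  )
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$log2_fold_change >= 0, "up", "down")
  attr(out, "excluded") <- excluded
  out
}

#' Baseline remission-versus-non-remission contrast with diagnosis adjustment
#'
#' Compares the two outcome groups at baseline with a negative binomial GLM
#' containing diagnosis and group factors; Wald test on the group coefficient.
#'
#' @inheritParams pairwise_de
#' @return data.frame in the [pairwise_de()] layout, contrast
#'   `"remission_vs_non_remission.baseline"`.
#' @export
baseline_contrast <- function(expr, design, shrink_weight = 0.5) {
  d <- design_subset(design, assay = "rna", timepoints = "baseline")
  if (length(unique(d$group)) < 2)
    stop_tnf("baseline contrast needs both outcome groups at baseline")
  for (g in unique(d$group)) {
    dg <- unique(d$diagnosis[d$group == g])
    if (length(dg) == 1 && length(unique(d$diagnosis)) > 1 &&
        !any(d$diagnosis == dg & d$group != g))
      stop_tnf("group '%s' lies entirely within diagnosis '%s'; group and diagnosis are confounded",
               g, dg)
  }
  if (is.null(expr$size_factors)) expr <- normalize_counts(expr)
  counts <- expr$counts[, d$sample_id, drop = FALSE]
  sf <- expr$size_factors[d$sample_id]
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  dd <- data.frame(diagnosis = factor(d$diagnosis),
                   group = factor(d$group, levels = c("non_remission", "remission")))
  form <- if (nlevels(dd$diagnosis) > 1) y ~ diagnosis + group else y ~ group
  mm <- stats::model.matrix(form[-2], dd)
  if (qr(mm)$rank < ncol(mm))
    stop_tnf("singular design: group and diagnosis are confounded")
  alpha <- moment_dispersions(sweep(counts, 2, sf, "/"),
                              interaction(dd$diagnosis, dd$group),
                              shrink_weight = shrink_weight)
  res <- t(vapply(seq_len(nrow(counts)), function(g)
    nb_wald(counts[g, ], dd, form, "groupremission", log(sf), alpha[g]),
    numeric(4)))
  out <- data.frame(
    gene_id = rownames(counts),
    contrast = "remission_vs_non_remission.baseline",
    log2_fold_change = res[, 1] / log(2),
    standard_error = res[, 2] / log(2),
    statistic = res[, 3],
    p_value = res[, 4],
    stringsAsFactors = FALSE
  )
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$log2_fold_change >= 0, "up", "down")
  out
}
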