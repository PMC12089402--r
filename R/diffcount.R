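#' Collapse technical replicates by summation
#'
#' Libraries sequenced from the same single-cell-derived clone are technical
#' replicates; their counts are summed into one clone-level column, mirroring
#' DESeq2's collapseReplicates behaviour.
#'
#' @param counts integer matrix, features x samples.
#' @param samples sample sheet rows matching the matrix columns.
#' @return list with the clone-level `counts` matrix and a clone-level
#'   `samples` data.frame (one row per clone, `sample_id == clone_id`).
#' @export
collapse_technical_replicates <- function(counts, samples) {
  stopifnot(ncol(counts) == nrow(samples))
  if (any(!colnames(counts) %in% samples$sample_id))
    stop("count columns not described in sample sheet")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  clones <- unique(samples$clone_id)
  out <- vapply(clones, function(cl) {
    idx <- which(samples$clone_id == cl)
    if (!length(idx)) stop("clone with zero samples: ", cl)
    rowSums(counts[, idx, drop = FALSE])
  }, numeric(nrow(counts)))
  out <- matrix(as.integer(out), nrow = nrow(counts),
                dimnames = list(rownames(counts), clones))
  meta <- samples[match(clones, samples$clone_id),
                  c("context", "genotype", "clone_id", "genotype_group"),
                  drop = FALSE]
  meta <- data.frame(sample_id = clones, meta, tech_rep = 1L,
                     stringsAsFactors = FALSE, row.names = NULL)
  list(counts = out, samples = meta)
}

#' Filter weakly expressed features
#'
#' Keeps features whose mean raw count across samples is strictly above
#' `min_mean`; genes at or below the threshold are removed before
#' normalisation and testing.
#'
#' @param counts raw (post-collapse) count matrix.
#' @param min_mean inclusive removal threshold on the row mean (default 5).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_mean = 5) {
  keep <- rowMeans(counts) > min_mean
  if (!any(keep)) message("filter_low_expression: no features pass (empty matrix returned)")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The DESeq-style depth estimator: each sample's size factor is the median,
#' over features detected in every sample, of the ratio of its count to the
#' feature's geometric mean across samples.
#'
#' @param counts raw count matrix.
#' @return list with `size_factors` (named, one per sample) and `normalized`
#'   (counts divided column-wise by the size factors).
#' @export
size_factors_median_of_ratios <- function(counts) {
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no feature is detected in every sample; cannot form the ",
         "geometric-mean reference set (pseudo-reference fallback is disabled)")
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(stats::median(col - loggeo)))
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per feature, `alpha = max(alpha_min, (s2 - mu) / mu^2)` with `mu` the grand
#' mean of normalised counts and `s2` the pooled within-group variance. No
#' empirical-Bayes shrinkage is applied. Features with zero mean are returned
#' as NA (untestable).
#'
#' @param normalized normalised count matrix.
#' @param groups per-sample group labels (two groups expected).
#' @param alpha_min dispersion floor (default 1e-8).
#' @return named numeric vector of dispersions (NA where untestable).
#' @export
estimate_dispersion <- function(normalized, groups, alpha_min = 1e-8) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(normalized))
  if (max(table(groups)) < 2) stop("need >= 2 samples in at least one group")
  mu <- rowMeans(normalized)
  ss <- 0; df <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    gm <- rowMeans(normalized[, idx, drop = FALSE])
    ss <- ss + rowSums((normalized[, idx, drop = FALSE] - gm)^2)
    df <- df + length(idx) - 1L
  }
  s2 <- ss / df
  alpha <- pmax(alpha_min, (s2 - mu) / mu^2)
  alpha[mu == 0] <- NA_real_
  names(alpha) <- rownames(normalized)
  alpha
}

# Newton iteration for the per-group NB mean parameter on the log scale,
# vectorised over features. With a saturated two-group design the GLM
# likelihood separates by group, so this is exactly the IRLS fit of the
# intercept + group-indicator model. Returns log-mean, Fisher information
# and a convergence flag per feature.
.nb_group_fit <- function(y, logsf, alpha, max_iter = 50L, tol = 1e-8) {
  nfeat <- nrow(y)
  mean_norm <- rowMeans(sweep(y, 2, exp(logsf), "/"))
  b <- log(mean_norm)            # all-zero rows handled by the caller
  conv <- rep(FALSE, nfeat)
  active <- rep(TRUE, nfeat)
  info <- rep(NA_real_, nfeat)
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    mu <- exp(outer(b[idx], logsf, "+"))
    w <- mu / (1 + alpha[idx] * mu)
    score <- rowSums((y[idx, , drop = FALSE] - mu) / (1 + alpha[idx] * mu))
    inf <- rowSums(w)
    step <- score / inf
    step <- pmin(pmax(step, -5), 5)   # damp early wild steps
    b[idx] <- b[idx] + step
    info[idx] <- inf
    done <- abs(step) <= tol * pmax(1, abs(b[idx]))
    conv[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }
  # refresh information at the final estimate for features that converged
  idx <- which(conv)
  if (length(idx)) {
    mu <- exp(outer(b[idx], logsf, "+"))
    info[idx] <- rowSums(mu / (1 + alpha[idx] * mu))
  }
  list(b = b, info = info, converged = conv)
}

#' Negative-binomial Wald test, controls vs mutants
#'
#' Fits, per feature, a two-group negative-binomial log-link GLM (CONTROL vs
#' MUTANT, i.e. WT vs pooled het + KO) with sample size factors as offsets and
#' a fixed method-of-moments dispersion, then tests the group coefficient with
#' a two-sided normal Wald test and applies Benjamini-Hochberg correction over
#' all tested features.
#'
#' Features where one group has only zero counts are reported with a capped
#' log2 fold change (+/- `lfc_cap`) and an undefined p-value, and are excluded
#' from the BH family; features with zero overall counts or failed fits are
#' untestable (all statistics NA).
#'
#' @param counts raw clone-level count matrix (post-collapse, post-filter).
#' @param samples clone-level sample sheet (needs `genotype_group`).
#' @param lfc_threshold absolute log2 fold-change bound of the significance
#'   call (default 1).
#' @param alpha adjusted-p cutoff of the significance call (default 0.1).
#' @param size_factors optional pre-computed size factors.
#' @param lfc_cap |log2FC| reported when one group is all-zero (default 10).
#' @param moderate_dispersion shrink each feature's method-of-moments
#'   dispersion toward the across-feature median, weighting the raw estimate
#'   by its residual degrees of freedom against `prior_df` pseudo-degrees
#'   (default TRUE). With a handful of clones the raw per-feature estimate is
#'   too noisy to test against; moderation stabilises both calibration and
#'   power, in the spirit of the shrinkage every count-based DE framework
#'   applies.
#' @param prior_df weight of the shared dispersion in the moderation
#'   (default 10).
#' @return data.frame with DESeq2-style columns `feature`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `significant`.
#' @export
nb_wald_test <- function(counts, samples, lfc_threshold = 1, alpha = 0.1,
                         size_factors = NULL, lfc_cap = 10,
                         moderate_dispersion = TRUE, prior_df = 10) {
  stopifnot(ncol(counts) == nrow(samples))
  grp <- samples$genotype_group[match(colnames(counts), samples$sample_id)]
  if (anyNA(grp)) stop("count columns not described in sample sheet")
  if (!all(c("CONTROL", "MUTANT") %in% grp)) stop("both groups must be non-empty")
  nr <- nrow(counts)
  if (is.null(size_factors)) {
    nf <- size_factors_median_of_ratios(counts)
  } else {
    nf <- list(size_factors = size_factors,
               normalized = sweep(counts, 2, size_factors, "/"))
  }
  logsf <- log(nf$size_factors)
  disp <- estimate_dispersion(nf$normalized, grp)
  if (moderate_dispersion && sum(!is.na(disp)) > 1) {
    res_df <- sum(pmax(table(grp) - 1L, 0L))
    disp0 <- stats::median(disp, na.rm = TRUE)
    disp <- (res_df * disp + prior_df * disp0) / (res_df + prior_df)
  }
  base_mean <- rowMeans(nf$normalized)

  res <- data.frame(feature = rownames(counts), baseMean = base_mean,
                    log2FoldChange = NA_real_, lfcSE = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)

  ctl <- grp == "CONTROL"; mut <- grp == "MUTANT"
  sum_c <- rowSums(counts[, ctl, drop = FALSE])
  sum_m <- rowSums(counts[, mut, drop = FALSE])

  zero_both <- sum_c == 0 & sum_m == 0
  one_zero <- xor(sum_c == 0, sum_m == 0)
  # one group all zero: capped LFC, no test, outside the BH family
  res$log2FoldChange[one_zero & sum_m == 0] <- -lfc_cap
  res$log2FoldChange[one_zero & sum_c == 0] <- lfc_cap
  if (any(one_zero)) {
    message(sum(one_zero), " feature(s) with one all-zero group: capped LFC, excluded from BH")
  }

  testable <- !zero_both & !one_zero & !is.na(disp)
  if (any(testable)) {
    y <- counts[testable, , drop = FALSE]
    a <- disp[testable]
    fit_c <- .nb_group_fit(y[, ctl, drop = FALSE], logsf[ctl], a)
    fit_m <- .nb_group_fit(y[, mut, drop = FALSE], logsf[mut], a)
    ok <- fit_c$converged & fit_m$converged
    beta <- fit_m$b - fit_c$b
    se <- sqrt(1 / fit_c$info + 1 / fit_m$info)
    z <- beta / se
    idx <- which(testable)[ok]
    res$log2FoldChange[idx] <- (beta / log(2))[ok]
    res$lfcSE[idx] <- (se / log(2))[ok]
    res$stat[idx] <- z[ok]
    res$pvalue[idx] <- (2 * stats::pnorm(-abs(z)))[ok]
    if (any(!ok)) message(sum(!ok), " feature(s) failed to converge: untestable")
  }

  tested <- !is.na(res$pvalue)
  if (any(tested)) res$padj[tested] <- benjamini_hochberg(res$pvalue[tested])
  res$significant <- !is.na(res$padj) & res$padj < alpha &
    abs(res$log2FoldChange) > lfc_threshold
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of defined p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (anyNA(pvals)) stop("benjamini_hochberg expects defined p-values only")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
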