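# Cohort summary and cytotoxicity-assay statistics.

# nearest whole percent, halves rounded up
.pct <- function(num, den) as.integer(floor(100 * num / den + 0.5))

#' Cohort mutation summary
#'
#' Counts patients carrying a qualifying non-synonymous mutation (allelic
#' fraction at or above `vaf_min`) and the disruptive fraction among them.
#' Percentages are reported to the nearest whole percent, counts exactly.
#'
#' @param cohort cohort data.frame (see [read_cohort()]).
#' @param vaf_min allelic-fraction inclusion cutoff (default 0.05).
#' @return list `n_total`, `n_mutant`, `pct_mutant`, `n_disruptive`,
#'   `pct_disruptive_of_mutant` (NA when there are no mutants).
#' @export
mutation_summary <- function(cohort, vaf_min = 0.05) {
  cohort <- validate_cohort(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  qual <- cohort$has_nonsyn_mutation & !is.na(cohort$allelic_fraction) &
    cohort$allelic_fraction >= vaf_min
  n_mut <- sum(qual)
  n_dis <- sum(qual & cohort$category == "disruptive")
  list(n_total = nrow(cohort), n_mutant = n_mut,
       pct_mutant = .pct(n_mut, nrow(cohort)),
       n_disruptive = n_dis,
       pct_disruptive_of_mutant = if (n_mut > 0) .pct(n_dis, n_mut) else NA_integer_)
}

#' Conjugate formation percentage
#'
#' Doubly labelled target/effector conjugates (CFSE+/VPD+) as a percentage of
#' effector cells (VPD+).
#'
#' @param double_pos_events CFSE+/VPD+ event count.
#' @param effector_events VPD+ event count (> 0).
#' @return percentage.
#' @export
conjugate_formation <- function(double_pos_events, effector_events) {
  stopifnot(double_pos_events >= 0)
  if (any(effector_events <= 0)) stop("effector_events must be > 0")
  100 * double_pos_events / effector_events
}

#' Specific cytotoxicity percentage
#'
#' Background-subtracted apoptosis: the AnnexinV-positive percentage of
#' co-cultured target cells minus that of target cells cultured alone,
#' floored at zero.
#'
#' @param annexin_pos_cocultured_pct percentage in [0, 100].
#' @param annexin_pos_alone_pct percentage in [0, 100].
#' @return percentage.
#' @export
specific_cytotoxicity <- function(annexin_pos_cocultured_pct, annexin_pos_alone_pct) {
  stopifnot(annexin_pos_cocultured_pct >= 0, annexin_pos_cocultured_pct <= 100,
            annexin_pos_alone_pct >= 0, annexin_pos_alone_pct <= 100)
  pmax(0, annexin_pos_cocultured_pct - annexin_pos_alone_pct)
}

#' Linear regression on square-root-transformed dose
#'
#' Ordinary least squares of the (untransformed) response on `sqrt(dose)`.
#' With groups, each non-reference group is tested against the reference
#' (first level) through its interaction with `sqrt(dose)`, Bonferroni
#' adjusted over the number of contrasts.
#'
#' @param dose non-negative doses.
#' @param response responses, same length.
#' @param group optional group labels; the first factor level (e.g. WT) is
#'   the reference.
#' @return list with `slope`, `intercept`, `p_slope` and, with groups, a
#'   `contrasts` data.frame (`group`, `estimate`, `p`, `p_bonferroni`).
#' @export
sqrt_dose_regression <- function(dose, response, group = NULL) {
  stopifnot(length(dose) == length(response), all(dose >= 0))
  if (length(unique(dose)) < 3) stop("need >= 3 distinct doses")
  sq <- sqrt(dose)
  if (is.null(group)) {
    fit <- stats::lm(response ~ sq)
    cf <- summary(fit)$coefficients
    return(list(slope = unname(cf["sq", "Estimate"]),
                intercept = unname(cf["(Intercept)", "Estimate"]),
                p_slope = unname(cf["sq", "Pr(>|t|)"])))
  }
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  fit <- stats::lm(response ~ sq * group)
  cf <- summary(fit)$coefficients
  rows <- grep("^sq:group", rownames(cf), value = TRUE)
  contrasts <- data.frame(group = sub("^sq:group", "", rows),
                          estimate = cf[rows, "Estimate"],
                          p = cf[rows, "Pr(>|t|)"],
                          stringsAsFactors = FALSE, row.names = NULL)
  contrasts$p_bonferroni <- pmin(1, contrasts$p * nrow(contrasts))
  list(slope = unname(cf["sq", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p_slope = unname(cf["sq", "Pr(>|t|)"]),
       contrasts = contrasts)
}

#' Assumption-guided two-group test
#'
#' The test-selection decision tree: Shapiro-Wilk normality per group at
#' alpha 0.05; if both groups look normal, Bartlett's variance test chooses
#' between the equal-variance t-test and the Welch test; otherwise the
#' Fligner-Killeen test chooses the Mann-Whitney U test when variances are
#' homogeneous, and falls back to the Welch test (with a warning) for
#' heterogeneous non-normal data, a case the tree does not cover. Bonferroni
#' adjustment multiplies p by `n_comparisons`, capped at 1.
#'
#' @param x,y the two sample vectors (each n >= 3).
#' @param n_comparisons number of comparisons in the family (default 1).
#' @param normality_alpha,variance_alpha assumption-test levels (default 0.05).
#' @return list `test_name`, `statistic`, `p`, `p_adjusted`.
#' @export
select_and_run_group_test <- function(x, y, n_comparisons = 1,
                                      normality_alpha = 0.05,
                                      variance_alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) stop("each group needs n >= 3 for the Shapiro test")
  normal <- stats::shapiro.test(x)$p.value >= normality_alpha &&
    stats::shapiro.test(y)$p.value >= normality_alpha
  vals <- c(x, y); grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (normal) {
    homo <- stats::bartlett.test(vals, grp)$p.value >= variance_alpha
    ht <- stats::t.test(x, y, var.equal = homo)
    test_name <- if (homo) "t-test" else "Welch"
  } else {
    homo <- stats::fligner.test(vals, grp)$p.value >= variance_alpha
    if (homo) {
      ht <- stats::wilcox.test(x, y, exact = FALSE)
      test_name <- "Mann-Whitney"
    } else {
      warning("non-normal data with heterogeneous variance: falling back to the Welch test")
      ht <- stats::t.test(x, y, var.equal = FALSE)
      test_name <- "Welch"
    }
  }
  list(test_name = test_name, statistic = unname(ht$statistic),
       p = ht$p.value, p_adjusted = min(1, ht$p.value * n_comparisons))
}
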