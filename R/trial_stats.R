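#' Absolute change from baseline
#'
#' @param baseline,followup Numeric vectors; pairs with a missing value give
#'   `NA` (the caller decides how to log exclusions).
#' @return `followup - baseline`; negative values are improvements for
#'   LVESVi, ECV and the serum biomarkers.
#' @examples
#' change_score(40, 36)  # -4
#' @export
change_score <- function(baseline, followup) {
  stopifnot(is.numeric(baseline), is.numeric(followup),
            length(baseline) == length(followup))
  followup - baseline
}

endpoint_columns <- function(cohort, outcome) {
  cols <- paste0(outcome, c("_baseline", "_6mo"))
  if (!all(cols %in% names(cohort)))
    stop(sprintf("cohort lacks columns %s", paste(cols, collapse = ", ")),
         call. = FALSE)
  cols
}

#' Genotype-stratified treatment effect on a change score
#'
#' For one genotype stratum, computes the 6-month change from baseline per
#' arm (mean, SD, n) and a two-sample t-test p-value comparing drug against
#' placebo. With `log_transform = TRUE` changes are computed on the
#' natural-log scale (records with a non-positive value at either visit are
#' excluded and counted). Complete-case analysis throughout.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] for the column
#'   dictionary); must contain `arm` and `<outcome>_baseline`,
#'   `<outcome>_6mo` columns.
#' @param outcome Endpoint stem, e.g. `"lvesvi"`, `"ntprobnp"`.
#' @param genotype Optional genotype (`"AA"`, `"AG"`, `"GG"`) to restrict to;
#'   `NULL` uses the whole cohort.
#' @param log_transform Compute changes as `log(6mo) - log(baseline)`.
#' @param var_equal Use the pooled-variance Student t-test instead of the
#'   default Welch (unequal-variance) test.
#' @return A list of class `stratified_effect` with `genotype`, `outcome`,
#'   `mean_change_drug`, `mean_change_placebo`, `sd_drug`, `sd_placebo`,
#'   `n_drug`, `n_placebo`, `p_value`, `n_excluded`.
#' @export
stratified_effect <- function(cohort, outcome, genotype = NULL,
                              log_transform = FALSE, var_equal = FALSE) {
  cols <- endpoint_columns(cohort, outcome)
  sub <- if (is.null(genotype)) cohort else cohort[cohort$genotype %in% genotype, ]
  if (nrow(sub) == 0L)
    stop("empty stratum: no records for the requested genotype", call. = FALSE)
  b <- sub[[cols[1]]]; f <- sub[[cols[2]]]
  ok <- !is.na(b) & !is.na(f) & !is.na(sub$arm)
  if (log_transform) ok <- ok & b > 0 & f > 0
  n_excluded <- sum(!ok)
  sub <- sub[ok, ]; b <- b[ok]; f <- f[ok]
  delta <- if (log_transform) log(f) - log(b) else f - b
  d_drug <- delta[sub$arm == "drug"]
  d_plac <- delta[sub$arm == "placebo"]
  if (length(d_drug) < 2L || length(d_plac) < 2L)
    stop("insufficient data: need >= 2 complete records per arm",
         call. = FALSE)
  tt <- stats::t.test(d_drug, d_plac, var.equal = var_equal)
  structure(
    list(genotype = if (is.null(genotype)) "all" else genotype,
         outcome = outcome,
         mean_change_drug = mean(d_drug),
         mean_change_placebo = mean(d_plac),
         sd_drug = stats::sd(d_drug), sd_placebo = stats::sd(d_plac),
         n_drug = length(d_drug), n_placebo = length(d_plac),
         p_value = tt$p.value, n_excluded = n_excluded,
         log_transform = log_transform),
    class = "stratified_effect")
}

#' @export
print.stratified_effect <- function(x, ...) {
  cat(sprintf(
    "<stratified_effect %s/%s: drug %.2f+/-%.2f (n=%d) vs placebo %.2f+/-%.2f (n=%d), p=%.3g>\n",
    x$outcome, x$genotype, x$mean_change_drug, x$sd_drug, x$n_drug,
    x$mean_change_placebo, x$sd_placebo, x$n_placebo, x$p_value))
  invisible(x)
}

#' Responder odds and odds ratio for LVESVi improvement
#'
#' A responder improves LVESVi by at least `improvement_fraction` of the
#' baseline value, i.e. `(baseline - followup) / baseline >=
#' improvement_fraction`. Per-arm odds are responders over non-responders and
#' the odds ratio is `odds_drug / odds_placebo`.
#'
#' @param cohort Cohort data frame with `arm`, `lvesvi_baseline`,
#'   `lvesvi_6mo`.
#' @param genotype Optional genotype stratum to restrict to.
#' @param improvement_fraction Relative improvement defining a responder
#'   (default 0.10, i.e. 10%).
#' @param correction Apply the Haldane-Anscombe 0.5 continuity correction to
#'   every cell (off by default); without it, a zero non-responder cell gives
#'   infinite odds, which is flagged.
#' @return A list of class `responder_odds`: per-arm responder /
#'   non-responder counts, `odds_drug`, `odds_placebo`, `odds_ratio`,
#'   `infinite_odds` flag.
#' @export
responder_odds <- function(cohort, genotype = NULL,
                           improvement_fraction = 0.10,
                           correction = FALSE) {
  cols <- endpoint_columns(cohort, "lvesvi")
  sub <- if (is.null(genotype)) cohort else cohort[cohort$genotype %in% genotype, ]
  b <- sub[[cols[1]]]; f <- sub[[cols[2]]]
  ok <- !is.na(b) & !is.na(f) & !is.na(sub$arm) & b > 0
  sub <- sub[ok, ]; b <- b[ok]; f <- f[ok]
  responder <- (b - f) / b >= improvement_fraction
  counts <- vapply(c("drug", "placebo"), function(a) {
    r <- responder[sub$arm == a]
    c(resp = sum(r), nonresp = sum(!r))
  }, numeric(2))
  if (any(colSums(counts) == 0))
    stop("an arm has no analyzable records", call. = FALSE)
  adj <- if (correction) 0.5 else 0
  odds <- (counts["resp", ] + adj) / (counts["nonresp", ] + adj)
  infinite <- any(!is.finite(odds))
  if (infinite)
    warning("zero non-responders in an arm: infinite odds", call. = FALSE)
  structure(
    list(n_responders_drug = counts["resp", "drug"],
         n_nonresponders_drug = counts["nonresp", "drug"],
         n_responders_placebo = counts["resp", "placebo"],
         n_nonresponders_placebo = counts["nonresp", "placebo"],
         odds_drug = unname(odds["drug"]),
         odds_placebo = unname(odds["placebo"]),
         odds_ratio = unname(odds["drug"] / odds["placebo"]),
         infinite_odds = infinite,
         improvement_fraction = improvement_fraction),
    class = "responder_odds")
}

#' @export
print.responder_odds <- function(x, ...) {
  cat(sprintf(
    "<responder_odds (>=%.0f%% LVESVi improvement): drug %.3g (%d/%d), placebo %.3g (%d/%d), OR=%.1f>\n",
    100 * x$improvement_fraction, x$odds_drug, x$n_responders_drug,
    x$n_nonresponders_drug, x$odds_placebo, x$n_responders_placebo,
    x$n_nonresponders_placebo, x$odds_ratio))
  invisible(x)
}

#' Rank correlation of fatty-acid change with LVESVi change
#'
#' Spearman correlation between the 6-month change in an RBC fatty-acid
#' measure (EPA, DHA or O3I) and the 6-month change in LVESVi. A negative
#' coefficient means larger fatty-acid rises track larger LVESVi reductions.
#'
#' @param cohort Cohort data frame with `<fatty_acid>_baseline/_6mo` and
#'   `lvesvi_baseline/_6mo` columns.
#' @param fatty_acid One of `"epa"`, `"dha"`, `"o3i"`.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
delta_correlation <- function(cohort, fatty_acid = c("epa", "dha", "o3i")) {
  fatty_acid <- match.arg(fatty_acid)
  fa_cols <- endpoint_columns(cohort, fatty_acid)
  lv_cols <- endpoint_columns(cohort, "lvesvi")
  d_fa <- change_score(cohort[[fa_cols[1]]], cohort[[fa_cols[2]]])
  d_lv <- change_score(cohort[[lv_cols[1]]], cohort[[lv_cols[2]]])
  ok <- !is.na(d_fa) & !is.na(d_lv)
  d_fa <- d_fa[ok]; d_lv <- d_lv[ok]
  if (length(d_fa) < 3L)
    stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(d_fa) == 0 || stats::sd(d_lv) == 0)
    stop("constant vector: rank correlation undefined", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(d_fa, d_lv, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(d_fa))
}

#' Baseline comparison across genotypes
#'
#' Chi-square test for categorical variables, one-way ANOVA for continuous
#' variables, comparing AA/AG/GG groups at baseline.
#'
#' @param cohort Cohort data frame with a `genotype` column.
#' @param variable Column name to compare.
#' @param type `"continuous"` (ANOVA) or `"categorical"` (chi-square).
#' @return A list with `p_value`, `statistic` (F or X-squared) and `method`.
#' @export
baseline_comparison <- function(cohort, variable,
                                type = c("continuous", "categorical")) {
  type <- match.arg(type)
  if (!variable %in% names(cohort))
    stop(sprintf("no column '%s' in cohort", variable), call. = FALSE)
  x <- cohort[[variable]]
  g <- cohort$genotype
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  if (nlevels(droplevels(g)) < 2L)
    stop("fewer than 2 genotype groups with data", call. = FALSE)
  if (type == "continuous") {
    if (any(tapply(x, g, length) < 2))
      stop("each genotype group needs >= 2 observations", call. = FALSE)
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    list(p_value = tab[["Pr(>F)"]][1], statistic = tab[["F value"]][1],
         method = "one-way ANOVA")
  } else {
    tab <- table(g, x)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p_value = ct$p.value, statistic = unname(ct$statistic),
         method = "chi-square")
  }
}

#' Bonferroni-adjusted paired visit test
#'
#' Paired Wilcoxon signed-rank test of 6-month against baseline values within
#' one subgroup, with the p-value multiplied by the number of parallel
#' comparisons (Bonferroni) and capped at 1.
#'
#' @param values_baseline,values_6mo Paired numeric vectors, equal length
#'   >= 5.
#' @param n_comparisons Number of simultaneous comparisons for the Bonferroni
#'   factor.
#' @return A list with `statistic` (signed-rank V), `p_value` (raw) and
#'   `p_adjusted`.
#' @export
paired_visit_test <- function(values_baseline, values_6mo, n_comparisons = 1) {
  stopifnot(length(values_baseline) == length(values_6mo))
  ok <- !is.na(values_baseline) & !is.na(values_6mo)
  b <- values_baseline[ok]; f <- values_6mo[ok]
  if (length(b) < 5L)
    stop("at least 5 complete pairs are required", call. = FALSE)
  if (all(f - b == 0))
    stop("all paired differences are zero: test degenerate", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(f, b, paired = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_comparisons))
}

#' Restrict a cohort to one racial category
#'
#' Used for the sensitivity re-analysis in the predominant racial subgroup;
#' every other operation composes with the filtered cohort.
#'
#' @param cohort Cohort data frame with a `race` column.
#' @param race Category to retain (default `"Caucasian"`).
#' @return The matching records; an empty result raises a warning, not an
#'   error.
#' @export
subgroup_filter <- function(cohort, race = "Caucasian") {
  if (!"race" %in% names(cohort))
    stop("cohort lacks a race column", call. = FALSE)
  out <- cohort[!is.na(cohort$race) & cohort$race == race, ]
  if (nrow(out) == 0L)
    warning(sprintf("no records with race '%s'", race), call. = FALSE)
  out
}

#' Median split
#'
#' Dichotomises a continuous measure at its sample median; values equal to
#' the median are labelled `"low"`.
#'
#' @param values Numeric vector with >= 2 non-missing values.
#' @return Character vector of `"low"`/`"high"` labels (`NA` preserved).
#' @examples
#' median_split(c(1, 2, 3, 4))  # low low high high
#' @export
median_split <- function(values) {
  if (sum(!is.na(values)) < 2L)
    stop("at least 2 non-missing values are required", call. = FALSE)
  med <- stats::median(values, na.rm = TRUE)
  if (isTRUE(all(values[!is.na(values)] == med)))
    warning("all values identical: degenerate median split", call. = FALSE)
  ifelse(is.na(values), NA_character_,
         ifelse(values <= med, "low", "high"))
}

#' Simple regression of a CMR variable on a biomarker
#'
#' Ordinary least squares of a CMR variable on a (optionally natural-log
#' transformed) biomarker level; records with missing values, or non-positive
#' biomarker values under the log transform, are excluded.
#'
#' @param cohort Cohort data frame.
#' @param biomarker,cmr_variable Column names (e.g. `"ntprobnp_baseline"`,
#'   `"lvesvi_baseline"`).
#' @param log_biomarker Natural-log transform the biomarker first.
#' @return A list with `slope`, `intercept`, `p_value` (slope test), `n`.
#' @export
biomarker_cmr_regression <- function(cohort, biomarker, cmr_variable,
                                     log_biomarker = FALSE) {
  for (v in c(biomarker, cmr_variable))
    if (!v %in% names(cohort))
      stop(sprintf("no column '%s' in cohort", v), call. = FALSE)
  x <- cohort[[biomarker]]
  y <- cohort[[cmr_variable]]
  ok <- !is.na(x) & !is.na(y)
  if (log_biomarker) ok <- ok & x > 0
  x <- x[ok]; y <- y[ok]
  if (log_biomarker) x <- log(x)
  if (length(x) < 3L)
    stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("singular design: biomarker is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = sm$coefficients[2, 4],
       n = length(x))
}
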