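# compact deterministic cohort for the statistical operations
make_fixture_cohort <- function(n = 60, seed = 13) {
  set.seed(seed)
  g <- rep(c("AA", "AG", "GG"), each = n / 3)
  arm <- rep(c("drug", "placebo"), n / 2)
  b <- stats::rlnorm(n, log(36), 0.3)
  data.frame(
    patient_id = sprintf("F%03d", 1:n),
    genotype = g, arm = arm,
    race = sample(c("Caucasian", "Black", "Hispanic"), n, TRUE,
                  prob = c(0.8, 0.1, 0.1)),
    lvesvi_baseline = b,
    lvesvi_6mo = b + stats::rnorm(n, ifelse(arm == "drug", -3, -1), 5),
    epa_baseline = stats::runif(n, 0.3, 1),
    epa_6mo = stats::runif(n, 0.3, 4),
    ntprobnp_baseline = stats::rlnorm(n, log(470), 0.9),
    stringsAsFactors = FALSE)
}

test_that("change scores subtract baseline row by row", {
  expect_equal(change_score(40, 36), -4)
  expect_equal(change_score(17.3, 17.3), 0)
  set.seed(1)
  b <- stats::rnorm(25, 40, 10); f <- stats::rnorm(25, 38, 10)
  got <- change_score(b, f)
  for (i in seq_along(b)) expect_identical(got[i], f[i] - b[i])
})

test_that("stratified effect matches the textbook Welch oracle", {
  d_drug <- c(-5, -4, -3); d_plac <- c(1, 2, 3)
  cohort <- data.frame(
    genotype = "GG", arm = rep(c("drug", "placebo"), each = 3),
    lvesvi_baseline = 40, lvesvi_6mo = 40 + c(d_drug, d_plac))
  eff <- stratified_effect(cohort, "lvesvi", genotype = "GG")
  expect_equal(eff$mean_change_drug, -4)
  expect_equal(eff$mean_change_placebo, 2)
  expect_equal(eff$p_value, oracle_welch_p(d_drug, d_plac), tolerance = 1e-12)

  # identical change distributions -> t = 0, p = 1
  sym <- data.frame(genotype = "AA",
                    arm = rep(c("drug", "placebo"), each = 4),
                    lvesvi_baseline = 40,
                    lvesvi_6mo = 40 + rep(c(-2, -1, 1, 2), 2))
  expect_equal(stratified_effect(sym, "lvesvi", "AA")$p_value, 1,
               tolerance = 1e-12)
})

test_that("a location shift of the placebo arm moves the contrast exactly", {
  cohort <- make_fixture_cohort()
  eff <- stratified_effect(cohort, "lvesvi", genotype = "AG")
  shifted <- cohort
  idx <- shifted$genotype == "AG" & shifted$arm == "placebo"
  shifted$lvesvi_6mo[idx] <- shifted$lvesvi_6mo[idx] + 2.5
  eff2 <- stratified_effect(shifted, "lvesvi", genotype = "AG")
  expect_equal(eff2$mean_change_placebo - eff$mean_change_placebo, 2.5)
  expect_equal(eff2$mean_change_drug, eff$mean_change_drug)
})

test_that("log-transformed effects drop non-positive values with bookkeeping", {
  cohort <- data.frame(
    genotype = "AA", arm = rep(c("drug", "placebo"), each = 4),
    ntprobnp_baseline = c(100, 200, 400, -5, 100, 200, 400, 800),
    ntprobnp_6mo = c(50, 100, 200, 100, 90, 210, 380, 800))
  eff <- stratified_effect(cohort, "ntprobnp", "AA", log_transform = TRUE)
  expect_equal(eff$n_excluded, 1)
  expect_equal(eff$n_drug, 3)
  expect_equal(eff$mean_change_drug, mean(log(c(50, 100, 200) / c(100, 200, 400))))
})

test_that("responder odds match the 2x2 enumeration and invert with arms", {
  cohort <- make_responder_cohort("GG", 3, 5, 1, 12)
  res <- responder_odds(cohort, genotype = "GG")
  expect_equal(res$odds_drug, 3 / 5)
  expect_equal(res$odds_placebo, 1 / 12)
  expect_equal(res$odds_ratio, (3 / 5) / (1 / 12))

  # equal odds in both arms -> OR 1
  eq <- make_responder_cohort("AA", 4, 6, 2, 3)
  expect_equal(responder_odds(eq, "AA")$odds_ratio, 1)

  # arm swap inverts the OR; patient order is irrelevant
  swapped <- cohort
  swapped$arm <- ifelse(cohort$arm == "drug", "placebo", "drug")
  expect_equal(responder_odds(swapped, "GG")$odds_ratio, 1 / res$odds_ratio)
  perm <- cohort[sample(nrow(cohort)), ]
  expect_equal(responder_odds(perm, "GG")$odds_ratio, res$odds_ratio)

  # synthetic binary outcomes against the brute-force count
  set.seed(6)
  cc <- make_fixture_cohort(90, seed = 6)
  res2 <- responder_odds(cc)
  imp <- (cc$lvesvi_baseline - cc$lvesvi_6mo) / cc$lvesvi_baseline >= 0.10
  a <- sum(imp & cc$arm == "drug"); b <- sum(!imp & cc$arm == "drug")
  c_ <- sum(imp & cc$arm == "placebo"); d <- sum(!imp & cc$arm == "placebo")
  expect_equal(res2$odds_ratio, (a / b) / (c_ / d))
})

test_that("zero non-responders flag infinite odds unless corrected", {
  cohort <- make_responder_cohort("GG", 5, 0, 2, 6)
  expect_warning(res <- responder_odds(cohort, "GG"), "infinite")
  expect_true(res$infinite_odds)
  res2 <- responder_odds(cohort, "GG", correction = TRUE)
  expect_equal(res2$odds_drug, 5.5 / 0.5)
})

test_that("delta correlation equals Pearson on midranks and is monotone-invariant", {
  # perfectly decreasing monotone relation -> -1
  cohort <- data.frame(
    genotype = "GG", arm = "drug",
    epa_baseline = 0, epa_6mo = 1:8,
    lvesvi_baseline = 0, lvesvi_6mo = -(1:8)^3)
  expect_equal(delta_correlation(cohort, "epa")$rho, -1)

  ten <- data.frame(
    genotype = "AA", arm = "drug",
    epa_baseline = 0,
    epa_6mo = c(1.2, 0.4, 2.2, 2.2, 0.9, 3.0, 1.7, 0.4, 2.6, 1.1),
    lvesvi_baseline = 0,
    lvesvi_6mo = c(-3, 1, -5, -4, 0, -7, -2, 2, -5, -1))
  got <- delta_correlation(ten, "epa")
  expect_equal(got$rho,
               oracle_spearman(ten$epa_6mo, ten$lvesvi_6mo),
               tolerance = 1e-12)

  # invariant under strictly monotone transforms of either variable
  tr <- ten
  tr$epa_6mo <- exp(tr$epa_6mo)
  tr$lvesvi_6mo <- tr$lvesvi_6mo^3
  expect_equal(delta_correlation(tr, "epa")$rho, got$rho)

  # independent large sample: near zero
  set.seed(99)
  big <- data.frame(genotype = "AA", arm = "drug",
                    epa_baseline = 0, epa_6mo = stats::rnorm(2000),
                    lvesvi_baseline = 0, lvesvi_6mo = stats::rnorm(2000))
  expect_lt(abs(delta_correlation(big, "epa")$rho), 0.08)

  const <- data.frame(genotype = "AA", arm = "drug",
                      epa_baseline = 0, epa_6mo = 1,
                      lvesvi_baseline = 0, lvesvi_6mo = c(1, 2, 3))
  expect_error(delta_correlation(const, "epa"), "constant")
})

test_that("baseline comparisons reproduce the ANOVA decomposition and chi-square nulls", {
  vals <- c(5.1, 6.2, 5.9, 7.4, 8.1, 7.7, 6.5, 6.0, 6.3)
  cohort <- data.frame(genotype = rep(c("AA", "AG", "GG"), each = 3),
                       bmi = vals)
  got <- baseline_comparison(cohort, "bmi", "continuous")
  expect_equal(got$statistic, oracle_anova_f(vals, cohort$genotype),
               tolerance = 1e-12)

  # balanced identical groups -> F = 0, p = 1
  same <- data.frame(genotype = rep(c("AA", "AG", "GG"), each = 4),
                     bmi = rep(c(1, 2, 3, 4), 3))
  res <- baseline_comparison(same, "bmi", "continuous")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # 2x3 table with equal rows -> chi-square 0
  cat_cohort <- data.frame(
    genotype = rep(c("AA", "AG", "GG"), each = 20),
    sex = rep(rep(c("F", "M"), each = 10), 3))
  res2 <- baseline_comparison(cat_cohort, "sex", "categorical")
  expect_equal(unname(res2$statistic), 0)
})

test_that("paired visit test matches exact signed-rank enumeration and caps at 1", {
  b <- as.numeric(1:8)
  f <- b + c(0.5, -1.2, 2.3, 3.1, -0.7, 1.9, 2.8, 4.0)
  got <- paired_visit_test(b, f)
  oc <- oracle_signed_rank(b, f)
  expect_equal(got$statistic, oc$statistic)
  expect_equal(got$p_value, oc$p_value, tolerance = 1e-12)

  # strictly increasing values at n = 20 are extreme
  set.seed(12)
  b2 <- stats::rnorm(20, 5, 1); f2 <- b2 + stats::runif(20, 0.5, 1.5)
  expect_lt(paired_visit_test(b2, f2)$p_value, 0.001)
  # Bonferroni cap
  expect_equal(paired_visit_test(b, f, n_comparisons = 1e6)$p_adjusted, 1)

  expect_error(paired_visit_test(1:4, 2:5), "at least 5")
  expect_error(paired_visit_test(1:6, 1:6), "degenerate")
})

test_that("subgroup filter retains matching records and composes", {
  cohort <- make_fixture_cohort()
  cauc <- subgroup_filter(cohort)
  expect_true(all(cauc$race == "Caucasian"))
  expect_warning(subgroup_filter(cohort, "Martian"), "no records")

  eff_filtered <- stratified_effect(cauc, "lvesvi", genotype = "AA")
  manual <- cohort[cohort$race == "Caucasian", ]
  eff_manual <- stratified_effect(manual, "lvesvi", genotype = "AA")
  expect_equal(eff_filtered$mean_change_drug, eff_manual$mean_change_drug)
  expect_equal(eff_filtered$p_value, eff_manual$p_value)
})

test_that("median split labels ties low and balances within tie count", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  expect_warning(median_split(c(2, 2, 2)), "degenerate")
  set.seed(44)
  v <- sample(1:20, 30, replace = TRUE)
  lab <- median_split(v)
  ties <- sum(v == stats::median(v))
  expect_lte(abs(sum(lab == "low") - sum(lab == "high")), ties)
})

test_that("biomarker regression recovers exact lines and the OLS oracle", {
  cohort <- data.frame(ntprobnp_baseline = c(1, 2, 3, 4),
                       lvesvi_baseline = 2 * c(1, 2, 3, 4) + 1)
  got <- suppressWarnings(  # summary.lm flags the zero-residual fixture
    biomarker_cmr_regression(cohort, "ntprobnp_baseline", "lvesvi_baseline"))
  expect_equal(got$slope, 2, tolerance = 1e-12)
  expect_equal(got$intercept, 1, tolerance = 1e-12)

  set.seed(7)
  cc <- data.frame(ntprobnp_baseline = stats::rlnorm(30, 6, 1),
                   lvesvi_baseline = stats::rnorm(30, 40, 8))
  got2 <- biomarker_cmr_regression(cc, "ntprobnp_baseline",
                                   "lvesvi_baseline", log_biomarker = TRUE)
  oc <- oracle_ols(log(cc$ntprobnp_baseline), cc$lvesvi_baseline)
  expect_equal(got2$slope, unname(oc["slope"]), tolerance = 1e-12)

  const <- data.frame(ntprobnp_baseline = rep(5, 10),
                      lvesvi_baseline = stats::rnorm(10))
  expect_error(biomarker_cmr_regression(const, "ntprobnp_baseline",
                                        "lvesvi_baseline"), "singular")
})
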