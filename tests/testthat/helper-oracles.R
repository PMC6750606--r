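# Independent oracle implementations used to cross-check the package.
# Deliberately brute-force / closed-form, sharing no code with R/.

# exhaustive lattice search for the IR model parameters minimising SSE
oracle_ir_grid <- function(ti, y, a_range, b_range, t1s_range, n_grid = 41) {
  a_seq <- seq(a_range[1], a_range[2], length.out = n_grid)
  b_seq <- seq(b_range[1], b_range[2], length.out = n_grid)
  t_seq <- seq(t1s_range[1], t1s_range[2], length.out = n_grid)
  best <- c(NA, NA, NA); best_sse <- Inf
  for (a in a_seq) for (b in b_seq) {
    for (tt in t_seq) {
      sse <- sum((y - (a - b * exp(-ti / tt)))^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(a, b, tt) }
    }
  }
  list(A = best[1], B = best[2], t1_star = best[3],
       t1 = best[3] * (best[2] / best[1] - 1), sse = best_sse)
}

# closed-form OLS slope/intercept
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(slope = slope, intercept = my - slope * mx)
}

# chi-square HWE statistic by direct arithmetic
oracle_hwe_stat <- function(n_aa, n_ag, n_gg) {
  n <- n_aa + n_ag + n_gg
  p <- (2 * n_aa + n_ag) / (2 * n)
  q <- 1 - p
  e <- c(n * p * p, 2 * n * p * q, n * q * q)
  o <- c(n_aa, n_ag, n_gg)
  sum((o - e)^2 / e)
}

# textbook Welch two-sample t-test p-value
oracle_welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

# midranks without rank(): average position of tied values
oracle_midrank <- function(x) {
  sorted <- sort(x)
  vapply(x, function(v) mean(which(sorted == v)), numeric(1))
}

# Spearman rho as Pearson correlation of midranks, coded from sums
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exact paired Wilcoxon signed-rank two-sided p by enumerating all 2^n
# sign assignments (requires distinct non-zero |differences|)
oracle_signed_rank <- function(baseline, followup) {
  d <- followup - baseline
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- oracle_midrank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(statistic = v_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# one-way ANOVA F statistic from the between/within decomposition
oracle_anova_f <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  levels <- unique(groups)
  ssb <- sum(vapply(levels, function(g) {
    v <- values[groups == g]; length(v) * (mean(v) - gm)^2
  }, numeric(1)))
  ssw <- sum(vapply(levels, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }, numeric(1)))
  dfb <- length(levels) - 1
  dfw <- length(values) - length(levels)
  (ssb / dfb) / (ssw / dfw)
}

# cohort fixture with hand-set responder counts per arm
make_responder_cohort <- function(genotype, n_resp_drug, n_nonresp_drug,
                                  n_resp_plac, n_nonresp_plac) {
  n <- n_resp_drug + n_nonresp_drug + n_resp_plac + n_nonresp_plac
  arm <- c(rep("drug", n_resp_drug + n_nonresp_drug),
           rep("placebo", n_resp_plac + n_nonresp_plac))
  responder <- c(rep(TRUE, n_resp_drug), rep(FALSE, n_nonresp_drug),
                 rep(TRUE, n_resp_plac), rep(FALSE, n_nonresp_plac))
  data.frame(patient_id = sprintf("X%03d", seq_len(n)),
             genotype = genotype, arm = arm,
             lvesvi_baseline = 100,
             # 15% improvement for responders, 0% for non-responders
             lvesvi_6mo = ifelse(responder, 85, 100),
             stringsAsFactors = FALSE)
}
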