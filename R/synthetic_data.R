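#' Imaging-phantom configuration
#'
#' Defines a noise-controllable digital phantom for the quantitative CMR
#' pipeline: per-timepoint blood and myocardial T1 values generated to lie
#' exactly on the partition-coefficient line `R1_myo = lambda * R1_blood +
#' intercept` before noise, plus an LGE slice with a planted hyperenhanced
#' region. The default blood T1 series (pre-contrast and 5/15/25 minutes
#' after gadolinium at 3 T) keeps blood R1 below 3.5 s^-1; setting
#' `include_early_timepoint = TRUE` adds a 1-minute point with blood R1 above
#' the exclusion boundary, whose myocardial R1 is generated off the line
#' (attenuated) to mimic the failure of fast water exchange.
#'
#' @param lambda_true Partition coefficient, in (0, 1).
#' @param intercept_true Intercept of the R1 line in s^-1.
#' @param hct Hematocrit fraction in (0, 1).
#' @param t1_blood_s Named numeric vector of blood T1 values (seconds) per
#'   timepoint.
#' @param include_early_timepoint Add the high-blood-R1 1-minute point.
#' @param b_over_a Inversion-recovery B/A ratio used for all curves
#'   (B/A = 2 is a perfect inversion; Look-Locker readouts give less).
#' @param a_signal Equilibrium signal amplitude A (arbitrary units).
#' @param inversion_times_s Inversion-time samples in seconds.
#' @param noise_sd IR signal noise SD (same units as `a_signal`); 0 gives a
#'   noise-free phantom.
#' @param n_segments Number of AHA segments simulated.
#' @param lge_positive_segments Indices of segments flagged LGE-positive.
#' @param grid_size LGE slice grid side length in pixels.
#' @param remote_mean,remote_sd Remote-myocardium LGE intensity mean and SD
#'   (the remote region carries a deterministic +/-1 SD texture so its sample
#'   SD is positive even at zero noise).
#' @param lge_noise_sd Additional Gaussian noise on LGE pixels.
#' @param pixel_area_mm2,slice_thickness_mm LGE pixel geometry.
#' @param seed Integer seed; all phantom randomness flows from it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(lambda_true = 0.57,
                           intercept_true = 1 / 1.2 - 0.57 / 1.9,
                           hct = 0.40,
                           t1_blood_s = c(pre = 1.9, `5min` = 0.45,
                                          `15min` = 0.60, `25min` = 0.80),
                           include_early_timepoint = FALSE,
                           b_over_a = 1.8,
                           a_signal = 1000,
                           inversion_times_s = seq(0.1, 3.0, by = 0.2),
                           noise_sd = 10,
                           n_segments = 16,
                           lge_positive_segments = c(1, 2),
                           grid_size = 32,
                           remote_mean = 100, remote_sd = 5,
                           lge_noise_sd = 0,
                           pixel_area_mm2 = 1, slice_thickness_mm = 8,
                           seed = 1L) {
  if (lambda_true <= 0 || lambda_true >= 1)
    stop("lambda_true must lie in (0, 1)", call. = FALSE)
  if (hct <= 0 || hct >= 1)
    stop("hct must lie in (0, 1)", call. = FALSE)
  if (b_over_a <= 1)
    stop("b_over_a must exceed 1 for a physical recovery", call. = FALSE)
  if (noise_sd < 0 || lge_noise_sd < 0 || remote_sd <= 0)
    stop("noise and texture SDs must be non-negative (remote_sd > 0)",
         call. = FALSE)
  if (any(t1_blood_s <= 0))
    stop("blood T1 values must be positive", call. = FALSE)
  cfg <- list(lambda_true = lambda_true, intercept_true = intercept_true,
              hct = hct, t1_blood_s = t1_blood_s,
              include_early_timepoint = include_early_timepoint,
              b_over_a = b_over_a, a_signal = a_signal,
              inversion_times_s = inversion_times_s, noise_sd = noise_sd,
              n_segments = n_segments,
              lge_positive_segments = lge_positive_segments,
              grid_size = grid_size, remote_mean = remote_mean,
              remote_sd = remote_sd, lge_noise_sd = lge_noise_sd,
              pixel_area_mm2 = pixel_area_mm2,
              slice_thickness_mm = slice_thickness_mm,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# curve with a given true T1 at a given B/A ratio: T1* = T1 / (B/A - 1)
make_ir_curve <- function(t1, cfg, label, noise) {
  t1_star <- t1 / (cfg$b_over_a - 1)
  A <- cfg$a_signal
  B <- cfg$b_over_a * A
  s <- ir_model(cfg$inversion_times_s, A, B, t1_star)
  if (cfg$noise_sd > 0) s <- s + noise
  ir_curve(cfg$inversion_times_s, s, label = label)
}

annulus_masks <- function(n) {
  cx <- (n + 1) / 2
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  dx <- idx$col - cx; dy <- idx$row - cx
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  myo <- matrix(r >= n / 5 & r <= n / 2.6, n, n)
  infarct <- myo & matrix(abs(theta) <= pi / 4, n, n)
  remote <- myo & matrix(abs(abs(theta) - pi) <= pi / 4, n, n)
  list(myocardium = myo, infarct = infarct, remote = remote)
}

#' Generate an imaging phantom
#'
#' Produces IR curves for every segment and the blood pool at every
#' timepoint (sampled from the signal model with the configured T1s), an LGE
#' slice with a planted infarct at `remote_mean + 6 * remote_sd`, and a
#' ground-truth record for closure assertions. Regeneration with the same
#' config (including seed) is bit-identical.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom` with elements `curves` (nested list:
#'   `curves[[timepoint]]$blood` and `curves[[timepoint]]$segments[[i]]`),
#'   `lge` (an [lge_slice()]), `truth` (lambda, intercept, hct, ecv, T1
#'   tables, planted infarct mask, ...), and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)

  t1_blood <- config$t1_blood_s
  r1_blood <- 1 / t1_blood
  r1_myo <- config$lambda_true * r1_blood + config$intercept_true
  if (config$include_early_timepoint) {
    r1b_early <- c(`1min` = 4.5)
    # fast water exchange fails at high blood [Gd]: myocardial R1 falls
    # short of the linear prediction
    r1m_early <- 0.8 * (config$lambda_true * r1b_early + config$intercept_true)
    r1_blood <- c(r1_blood[1], r1b_early, r1_blood[-1])
    r1_myo <- c(r1_myo[1], r1m_early, r1_myo[-1])
  }
  t1_blood_all <- 1 / r1_blood
  t1_myo_all <- 1 / r1_myo
  timepoints <- names(r1_blood)

  n_ti <- length(config$inversion_times_s)
  curves <- lapply(seq_along(timepoints), function(k) {
    blood <- make_ir_curve(t1_blood_all[k], config,
                           paste0("blood_", timepoints[k]),
                           stats::rnorm(n_ti, 0, config$noise_sd))
    segments <- lapply(seq_len(config$n_segments), function(s)
      make_ir_curve(t1_myo_all[k], config,
                    sprintf("seg%02d_%s", s, timepoints[k]),
                    stats::rnorm(n_ti, 0, config$noise_sd)))
    list(blood = blood, segments = segments)
  })
  names(curves) <- timepoints

  masks <- annulus_masks(config$grid_size)
  img <- matrix(0, config$grid_size, config$grid_size)
  img[masks$myocardium] <- config$remote_mean
  # deterministic +/-1 SD texture keeps the remote sample SD positive even
  # in the noise-free phantom
  remote_idx <- which(masks$remote)
  img[remote_idx] <- config$remote_mean +
    config$remote_sd * rep_len(c(-1, 1), length(remote_idx))
  img[masks$infarct] <- config$remote_mean + 6 * config$remote_sd
  if (config$lge_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, config$lge_noise_sd),
                        nrow(img), ncol(img))
  lge <- lge_slice(img, masks$myocardium, masks$remote,
                   config$pixel_area_mm2, config$slice_thickness_mm)

  truth <- list(
    lambda = config$lambda_true,
    intercept = config$intercept_true,
    hct = config$hct,
    ecv = config$lambda_true * (1 - config$hct),
    t1_blood_s = t1_blood_all,
    t1_myo_s = t1_myo_all,
    excluded_timepoints = timepoints[r1_blood >= 3.5],
    A = config$a_signal,
    B = config$b_over_a * config$a_signal,
    infarct_mask = masks$infarct,
    lge_positive_segments = config$lge_positive_segments)

  structure(list(curves = curves, lge = lge, truth = truth, config = config),
            class = "phantom")
}

default_change_params <- function() {
  g <- c("AA", "AG", "GG")
  m <- function(...) matrix(c(...), nrow = 3, byrow = TRUE,
                            dimnames = list(g, c("drug", "placebo")))
  list(
    lvesvi = list(mean = m(-2.5, -1.0, -3.6, -1.2, -4.4, 1.2),
                  sd   = m(6.7, 8.3, 6.6, 7.8, 5.6, 4.1)),
    lvedvi = list(mean = m(-1.2, -0.2, -2.9, -0.6, -4.2, 2.3),
                  sd   = m(12.4, 13.2, 12.3, 12.5, 9.5, 8.3)),
    ecv_noninfarct = list(mean = m(-2.0, -1.1, -1.0, 3.1, 2.0, -2.9),
                          sd   = m(5.2, 4.2, 5.6, 7.8, 5.3, 2.0)),
    infarct_size = list(mean = m(-3.4, -1.3, 0.03, -1.6, -1.8, -3.5),
                        sd   = m(8.2, 7.1, 5.4, 6.4, 9.7, 10.2)),
    lvef = list(mean = m(2.3, 1.1, 2.8, 1.1, 2.4, 0.02),
                sd   = m(5.8, 6.5, 4.9, 7.1, 4.6, 4.8)),
    # only the GG biomarker cells are pinned by the study summaries; AA/AG
    # cells are arm-similar values consistent with the overall-cohort means
    ntprobnp = list(mean = m(-550, -600, -550, -600, -733, -181),
                    sd   = m(1000, 1300, 1000, 1300, 672, 139)),
    galectin3 = list(mean = m(-0.6, -0.1, -0.6, -0.1, -1.96, 0.51),
                     sd   = m(4.7, 3.6, 4.7, 3.6, 4.16, 3.97)),
    lipoprotein_a = list(mean = m(-1.0, 0.0, -4.0, 0.0, -8.4, 0.43),
                         sd   = m(8.0, 8.0, 8.0, 8.0, 7.62, 8.26)),
    hscrp = list(mean = m(-0.3, -0.3, -0.3, -0.3, -0.3, -0.3),
                 sd   = m(6, 6, 6, 6, 6, 6)))
}

#' Trial-cohort configuration
#'
#' Distributional parameters for the synthetic post-MI cohort. The defaults
#' are the published trial summaries: 312 genotyped patients, minor-G allele
#' frequency 190/624 (so Hardy-Weinberg expectations are close to the
#' observed 156/122/34 split), ArA/LA means 2.01/1.76/1.62 (SD 0.35) for
#' AA/AG/GG, and per-(genotype x arm) 6-month change means/SDs for LVESVi,
#' LVEDVi, non-infarct ECV, infarct size, LVEF, NT-proBNP, galectin-3,
#' lipoprotein(a) and hsCRP. Drug-arm rises in EPA/DHA are coupled to the
#' LVESVi change through a Gaussian copula targeting the configured Spearman
#' correlations.
#'
#' @param n_patients Cohort size.
#' @param freq_g Minor (G) allele frequency; genotypes are drawn from
#'   Hardy-Weinberg proportions.
#' @param arm_ratio Probability of assignment to the drug arm.
#' @param arala_means Named vector of ArA/LA means for AA/AG/GG.
#' @param arala_sd Common ArA/LA SD.
#' @param change_params Nested list of per-endpoint `mean`/`sd` 3x2 matrices
#'   (genotype x arm); see `omegacmr:::default_change_params()`.
#' @param o3fa_rise_mean,o3fa_rise_sd Named vectors (`epa`, `dha`) of the
#'   6-month rise mean/SD in the drug arm, percent of RBC fatty acids.
#' @param placebo_rise_mean,placebo_rise_sd Same for the placebo arm.
#' @param delta_correlation_target Named vector (`epa`, `dha`) of target
#'   Spearman correlations between the fatty-acid rise and the LVESVi change
#'   on the residual (latent) scale; O3I inherits its coupling as EPA + DHA.
#' @param caucasian_prob Named vector of P(Caucasian) per genotype.
#' @param seed Integer seed; all cohort randomness flows from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 312,
                          freq_g = 190 / 624,
                          arm_ratio = 0.5,
                          arala_means = c(AA = 2.01, AG = 1.76, GG = 1.62),
                          arala_sd = 0.35,
                          change_params = default_change_params(),
                          o3fa_rise_mean = c(epa = 2.0, dha = 2.2),
                          o3fa_rise_sd = c(epa = 1.0, dha = 1.3),
                          placebo_rise_mean = c(epa = 0.05, dha = 0.05),
                          placebo_rise_sd = c(epa = 0.3, dha = 0.5),
                          delta_correlation_target = c(epa = -0.17,
                                                       dha = -0.31),
                          caucasian_prob = c(AA = 0.78, AG = 0.81, GG = 0.91),
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (freq_g < 0 || freq_g > 1)
    stop("freq_g must lie in [0, 1]", call. = FALSE)
  if (arm_ratio < 0 || arm_ratio > 1)
    stop("arm_ratio must lie in [0, 1]", call. = FALSE)
  if (arala_sd < 0) stop("arala_sd must be non-negative", call. = FALSE)
  for (ep in change_params)
    if (any(ep$sd < 0)) stop("change SDs must be non-negative", call. = FALSE)
  if (any(abs(delta_correlation_target) >= 1))
    stop("rank-correlation targets must lie in (-1, 1)", call. = FALSE)
  cfg <- list(n_patients = as.integer(n_patients), freq_g = freq_g,
              arm_ratio = arm_ratio, arala_means = arala_means,
              arala_sd = arala_sd, change_params = change_params,
              o3fa_rise_mean = o3fa_rise_mean, o3fa_rise_sd = o3fa_rise_sd,
              placebo_rise_mean = placebo_rise_mean,
              placebo_rise_sd = placebo_rise_sd,
              delta_correlation_target = delta_correlation_target,
              caucasian_prob = caucasian_prob, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

rlnorm_med <- function(n, median, sdlog) stats::rlnorm(n, log(median), sdlog)

#' Generate a synthetic trial cohort
#'
#' Draws a cohort with genotypes in Hardy-Weinberg proportions, randomized
#' arms, genotype-dependent ArA/LA ratios, and per-(genotype x arm) Normal
#' 6-month changes in the CMR endpoints and serum biomarkers. Baselines are
#' drawn from log-normal or Normal distributions matching the published
#' baseline tables; follow-up values are baseline + change. Drug-arm rises
#' in EPA and DHA share a Gaussian-copula latent variable with the LVESVi
#' change so their rank correlation approximates the configured target (the
#' achieved correlation should be verified empirically, not assumed). The
#' change draws are independent of baseline, so occasional records can show
#' a negative follow-up infarct size or biomarker level; they are retained
#' so the configured change distributions stay exact.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `cohort` (data frame, one row
#'   per patient, columns `patient_id`, `genotype`, `arm`, `race`, `hct`,
#'   `<endpoint>_baseline`/`_6mo` for lvesvi, lvedvi, ecv_noninfarct,
#'   infarct_size, lvef, ntprobnp, galectin3, lipoprotein_a, hscrp, epa,
#'   dha, o3i, plus `ara_pct`, `la_pct`, `ala_pct`, `arala_ratio`) and
#'   `truth` (the generating parameters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  q <- config$freq_g; p <- 1 - q

  genotype <- sample(c("AA", "AG", "GG"), n, replace = TRUE,
                     prob = c(p^2, 2 * p * q, q^2))
  arm <- sample(c("drug", "placebo"), n, replace = TRUE,
                prob = c(config$arm_ratio, 1 - config$arm_ratio))
  cauc <- stats::runif(n) < config$caucasian_prob[genotype]
  race <- ifelse(cauc, "Caucasian",
                 sample(c("Hispanic", "Black", "Other"), n, replace = TRUE,
                        prob = c(0.37, 0.35, 0.28)))
  hct <- pmin(pmax(stats::rnorm(n, 0.395, 0.05), 0.20), 0.60)

  # baselines (medians / spreads from the published baseline tables)
  lvesvi_med <- c(AA = 35, AG = 36, GG = 38)[genotype]
  lvesvi_b <- rlnorm_med(n, lvesvi_med, 0.35)
  lvedvi_b <- pmax(stats::rnorm(n, c(AA = 82, AG = 84, GG = 87)[genotype], 20),
                   30)
  ecv_b <- stats::rnorm(n, c(AA = 34, AG = 34, GG = 35)[genotype], 5)
  infarct_b <- rlnorm_med(n, c(AA = 14, AG = 12, GG = 18)[genotype], 0.8)
  lvef_b <- pmin(pmax(
    stats::rnorm(n, c(AA = 54, AG = 55, GG = 52)[genotype], 9), 15), 80)
  ntprobnp_b <- rlnorm_med(n, 470, 0.95)
  galectin3_b <- rlnorm_med(n, 15, 0.34)
  lipoprotein_a_b <- rlnorm_med(n, 27, 1.2)
  hscrp_b <- rlnorm_med(n, 2.5, 1.3)

  # fatty-acid profile: ArA/LA ratio by genotype, individual percentages
  arala <- pmax(stats::rnorm(n, config$arala_means[genotype],
                             config$arala_sd), 0.2)
  la_pct <- pmax(stats::rnorm(n, 11, 1.2), 5)
  ara_pct <- arala * la_pct
  ala_pct <- pmax(stats::rnorm(n, 0.2, 0.08), 0.02)
  epa_b <- pmax(stats::rnorm(n, 0.6, 0.25), 0.1)
  dha_b <- pmax(stats::rnorm(n, 4.3, 1.1), 0.5)

  # per-(genotype x arm) endpoint changes; the LVESVi latent z is shared
  # with the fatty-acid rises through a Gaussian copula
  cell <- cbind(genotype, arm)
  changes <- list()
  z_lvesvi <- stats::rnorm(n)
  for (ep in names(config$change_params)) {
    par <- config$change_params[[ep]]
    mu <- par$mean[cell]; sd <- par$sd[cell]
    z <- if (ep == "lvesvi") z_lvesvi else stats::rnorm(n)
    changes[[ep]] <- mu + sd * z
  }

  # Spearman rho_s maps to latent Gaussian correlation 2 sin(pi rho_s / 6)
  latent_rho <- 2 * sin(pi * config$delta_correlation_target / 6)
  rise <- list()
  for (fa in c("epa", "dha")) {
    rho <- latent_rho[[fa]]
    z_fa <- rho * z_lvesvi + sqrt(1 - rho^2) * stats::rnorm(n)
    mu <- ifelse(arm == "drug", config$o3fa_rise_mean[[fa]],
                 config$placebo_rise_mean[[fa]])
    sd <- ifelse(arm == "drug", config$o3fa_rise_sd[[fa]],
                 config$placebo_rise_sd[[fa]])
    rise[[fa]] <- mu + sd * z_fa
  }
  epa_f <- pmax(epa_b + rise$epa, 0.05)
  dha_f <- pmax(dha_b + rise$dha, 0.2)

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    genotype = genotype, arm = arm, race = race, hct = hct,
    lvesvi_baseline = lvesvi_b, lvesvi_6mo = lvesvi_b + changes$lvesvi,
    lvedvi_baseline = lvedvi_b, lvedvi_6mo = lvedvi_b + changes$lvedvi,
    ecv_noninfarct_baseline = ecv_b,
    ecv_noninfarct_6mo = ecv_b + changes$ecv_noninfarct,
    infarct_size_baseline = infarct_b,
    infarct_size_6mo = infarct_b + changes$infarct_size,
    lvef_baseline = lvef_b, lvef_6mo = lvef_b + changes$lvef,
    ntprobnp_baseline = ntprobnp_b,
    ntprobnp_6mo = ntprobnp_b + changes$ntprobnp,
    galectin3_baseline = galectin3_b,
    galectin3_6mo = galectin3_b + changes$galectin3,
    lipoprotein_a_baseline = lipoprotein_a_b,
    lipoprotein_a_6mo = lipoprotein_a_b + changes$lipoprotein_a,
    hscrp_baseline = hscrp_b, hscrp_6mo = hscrp_b + changes$hscrp,
    epa_baseline = epa_b, epa_6mo = epa_f,
    dha_baseline = dha_b, dha_6mo = dha_f,
    o3i_baseline = epa_b + dha_b, o3i_6mo = epa_f + dha_f,
    ara_pct = ara_pct, la_pct = la_pct, ala_pct = ala_pct,
    arala_ratio = arala,
    stringsAsFactors = FALSE)

  truth <- list(
    freq_g = q,
    genotype_probs = c(AA = p^2, AG = 2 * p * q, GG = q^2),
    arm_ratio = config$arm_ratio,
    arala_means = config$arala_means, arala_sd = config$arala_sd,
    change_params = config$change_params,
    o3fa_rise_mean = config$o3fa_rise_mean,
    o3fa_rise_sd = config$o3fa_rise_sd,
    delta_correlation_target = config$delta_correlation_target,
    latent_rho = latent_rho,
    seed = config$seed)

  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$cohort$genotype)
  cat(sprintf("<synthetic_cohort: n=%d (AA=%d AG=%d GG=%d), seed=%d>\n",
              nrow(x$cohort), tab[["AA"]], tab[["AG"]], tab[["GG"]],
              x$truth$seed))
  invisible(x)
}
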