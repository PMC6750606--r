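#' Run every quantitative-imaging stage on a phantom
#'
#' Fits the inversion-recovery model to every blood and segment curve at
#' every timepoint, converts corrected T1s to R1, estimates the per-segment
#' partition coefficient and ECV (with the blood R1 < 3.5 s^-1 exclusion),
#' aggregates non-infarct ECV over LGE-negative segments, and segments the
#' infarct on the LGE slice at the 2-SD threshold.
#'
#' @param phantom A phantom bundle from [generate_phantom()].
#' @return A list with `t1_fits` (data frame: timepoint, label, A, B,
#'   t1_star_s, t1_s, converged), `segment_ecv` (per-segment `ecv_fit`
#'   list), `ecv_map` (a [segmental_ecv_map()]), `ecv_noninfarct`
#'   (fraction), `lambda_mean` (mean per-segment slope), `infarct`
#'   (an `infarct_result`).
#' @export
analyze_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  timepoints <- names(phantom$curves)
  n_seg <- phantom$config$n_segments

  fits <- list()
  t1_blood <- numeric(length(timepoints))
  t1_myo <- matrix(NA_real_, n_seg, length(timepoints),
                   dimnames = list(NULL, timepoints))
  for (k in seq_along(timepoints)) {
    tp <- timepoints[k]
    bf <- fit_inversion_recovery(phantom$curves[[tp]]$blood)
    t1_blood[k] <- bf$t1
    fits[[length(fits) + 1L]] <- data.frame(
      timepoint = tp, label = bf$label, A = bf$A, B = bf$B,
      t1_star_s = bf$t1_star, t1_s = bf$t1, converged = bf$converged)
    for (s in seq_len(n_seg)) {
      sf <- fit_inversion_recovery(phantom$curves[[tp]]$segments[[s]])
      t1_myo[s, k] <- sf$t1
      fits[[length(fits) + 1L]] <- data.frame(
        timepoint = tp, label = sf$label, A = sf$A, B = sf$B,
        t1_star_s = sf$t1_star, t1_s = sf$t1, converged = sf$converged)
    }
  }

  r1_blood <- compute_r1(t1_blood)
  segment_ecv <- lapply(seq_len(n_seg), function(s)
    estimate_ecv(r1_pairs(r1_blood, compute_r1(t1_myo[s, ]), timepoints),
                 hct = phantom$truth$hct))
  ecv_values <- vapply(segment_ecv, `[[`, numeric(1), "ecv")
  lge_pos <- seq_len(n_seg) %in% phantom$truth$lge_positive_segments
  # clipping guards the map container invariant under extreme noise only;
  # noise-free values land strictly inside (0, 1)
  ecv_map <- segmental_ecv_map(sprintf("seg%02d", seq_len(n_seg)),
                               pmin(pmax(ecv_values, 0), 1), lge_pos)

  infarct <- segment_infarct(phantom$lge)

  list(t1_fits = do.call(rbind, fits),
       segment_ecv = segment_ecv,
       ecv_map = ecv_map,
       ecv_noninfarct = aggregate_noninfarct_ecv(ecv_map),
       lambda_mean = mean(vapply(segment_ecv, `[[`, numeric(1), "lambda")),
       infarct = infarct)
}

#' Genotype-stratified analysis report
#'
#' Computes the full stratified treatment-effect table: per-genotype
#' per-arm 6-month changes with t-test p-values for every endpoint,
#' responder odds ratios for >= 10% LVESVi improvement, overall-cohort
#' effects, fatty-acid/LVESVi rank correlations, and the Hardy-Weinberg
#' check of the genotype distribution.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for columns).
#' @param endpoints Endpoint stems to tabulate.
#' @param improvement_fraction Responder definition for the odds ratios.
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @param race_filter Optional race category; when given, the analysis runs
#'   on [subgroup_filter()]'s output.
#' @param log_endpoints Endpoints analysed on the natural-log scale (in
#'   addition to the natural-units row).
#' @return A list of class `cohort_report` with `effects` (tidy data
#'   frame), `odds` (per-genotype `responder_odds`), `overall` (unstratified
#'   effects), `correlations`, `hwe`, `genotype_table`, `n`.
#' @export
analyze_cohort <- function(cohort,
                           endpoints = c("lvesvi", "lvedvi",
                                         "ecv_noninfarct", "infarct_size",
                                         "lvef", "ntprobnp", "galectin3",
                                         "lipoprotein_a", "hscrp"),
                           improvement_fraction = 0.10,
                           var_equal = FALSE,
                           race_filter = NULL,
                           log_endpoints = character()) {
  if (!is.null(race_filter)) cohort <- subgroup_filter(cohort, race_filter)
  genos <- c("AA", "AG", "GG")

  rows <- list()
  for (ep in endpoints) {
    for (g in genos) {
      eff <- tryCatch(
        stratified_effect(cohort, ep, genotype = g, var_equal = var_equal,
                          log_transform = ep %in% log_endpoints),
        error = function(e) NULL)
      if (is.null(eff)) next
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, genotype = g,
        mean_change_drug = eff$mean_change_drug, sd_drug = eff$sd_drug,
        n_drug = eff$n_drug,
        mean_change_placebo = eff$mean_change_placebo,
        sd_placebo = eff$sd_placebo, n_placebo = eff$n_placebo,
        p_value = eff$p_value)
    }
  }
  effects <- do.call(rbind, rows)

  odds <- lapply(stats::setNames(genos, genos), function(g)
    tryCatch(responder_odds(cohort, genotype = g,
                            improvement_fraction = improvement_fraction),
             error = function(e) NULL))

  overall <- lapply(stats::setNames(endpoints, endpoints), function(ep)
    tryCatch(stratified_effect(cohort, ep, var_equal = var_equal,
                               log_transform = ep %in% log_endpoints),
             error = function(e) NULL))

  correlations <- lapply(stats::setNames(c("epa", "dha", "o3i"),
                                         c("epa", "dha", "o3i")),
                         function(fa)
    tryCatch(delta_correlation(cohort, fa), error = function(e) NULL))

  tab <- table(factor(cohort$genotype, levels = genos))
  gt <- genotype_table(tab[["AA"]], tab[["AG"]], tab[["GG"]])

  structure(
    list(effects = effects, odds = odds, overall = overall,
         correlations = correlations,
         hwe = suppressWarnings(hwe_chi_square(gt)),
         genotype_table = gt, n = nrow(cohort)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: n=%d, %d endpoint x genotype rows>\n",
              x$n, nrow(x$effects)))
  ors <- vapply(x$odds, function(o)
    if (is.null(o)) NA_real_ else o$odds_ratio, numeric(1))
  cat(sprintf("  OR(>=10%% LVESVi improvement): AA=%.1f AG=%.1f GG=%.1f\n",
              ors[["AA"]], ors[["AG"]], ors[["GG"]]))
  invisible(x)
}

#' Pipeline run configuration
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed driving both generators.
#' @param phantom A [phantom_config()]; `NULL` skips the imaging stages.
#' @param cohort A [cohort_config()]; `NULL` skips the cohort stages.
#' @param cohort_csv Optional path to an existing cohort CSV (used instead
#'   of the generator).
#' @param column_map Optional column-name mapping for `cohort_csv` (see
#'   [ingest_cohort()]).
#' @param improvement_fraction,var_equal,race_filter,log_endpoints Analysis
#'   options forwarded to [analyze_cohort()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("omegacmr_run_"),
                       seed = 1L,
                       phantom = phantom_config(seed = seed),
                       cohort = cohort_config(seed = seed),
                       cohort_csv = NULL, column_map = NULL,
                       improvement_fraction = 0.10, var_equal = FALSE,
                       race_filter = NULL, log_endpoints = character()) {
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("cohort_csv does not exist", call. = FALSE)
  structure(
    list(outdir = outdir, seed = as.integer(seed), phantom = phantom,
         cohort = cohort, cohort_csv = cohort_csv, column_map = column_map,
         improvement_fraction = improvement_fraction, var_equal = var_equal,
         race_filter = race_filter, log_endpoints = log_endpoints),
    class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate -> relaxometry -> ECV -> infarct -> cohort assembly ->
#' stratified statistics, writing per-stage outputs (tidy CSV) and a
#' machine-readable JSON run report (software version, seed, config hash;
#' no timestamps, so reruns with the same config and seed are
#' byte-identical).
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly; also written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package = "omegacmr",
    version = as.character(utils::packageVersion("omegacmr")),
    seed = config$seed,
    config_hash = config_hash(config))

  if (!is.null(config$phantom)) {
    phantom <- generate_phantom(config$phantom)
    imaging <- analyze_phantom(phantom)
    utils::write.csv(imaging$t1_fits,
                     file.path(config$outdir, "t1_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(imaging$ecv_map,
                     file.path(config$outdir, "segment_ecv.csv"),
                     row.names = FALSE)
    report$imaging <- list(
      lambda_mean = imaging$lambda_mean,
      ecv_noninfarct = imaging$ecv_noninfarct,
      lambda_true = phantom$truth$lambda,
      ecv_true = phantom$truth$ecv,
      infarct_threshold = imaging$infarct$threshold,
      infarct_mass_g = imaging$infarct$infarct_mass_g,
      infarct_pct_lv = imaging$infarct$infarct_pct_lv,
      lv_mass_g = imaging$infarct$lv_mass_g)
  }

  cohort <- NULL
  if (!is.null(config$cohort_csv)) {
    cohort <- ingest_cohort(config$cohort_csv, column_map = config$column_map)
  } else if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)$cohort
    utils::write.csv(cohort, file.path(config$outdir, "cohort.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort)) {
    rep_c <- analyze_cohort(
      cohort, improvement_fraction = config$improvement_fraction,
      var_equal = config$var_equal, race_filter = config$race_filter,
      log_endpoints = config$log_endpoints)
    utils::write.csv(rep_c$effects,
                     file.path(config$outdir, "stratified_effects.csv"),
                     row.names = FALSE)
    report$cohort <- list(
      n = rep_c$n,
      genotype_counts = unclass(rep_c$genotype_table)[c("n_aa", "n_ag",
                                                        "n_gg")],
      hwe_statistic = rep_c$hwe$statistic,
      hwe_p = rep_c$hwe$p_value,
      odds_ratio = lapply(rep_c$odds, function(o)
        if (is.null(o)) NULL else o$odds_ratio),
      correlations = lapply(rep_c$correlations, function(x)
        if (is.null(x)) NULL else x[c("rho", "p_value")]))
    report$effects_table <- rep_c$effects
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

config_hash <- function(config) {
  # seed + structural options only; stable across sessions
  key <- utils::capture.output(utils::str(
    config[setdiff(names(config), "outdir")], give.attr = FALSE))
  sum(utf8ToInt(paste(key, collapse = "\n")) *
        (seq_along(utf8ToInt(paste(key, collapse = "\n"))) %% 97 + 1)) %% 1e9
}

required_cohort_columns <- c("patient_id", "genotype", "arm")

#' Ingest an external cohort table
#'
#' Reads a cohort from CSV (or XLSX, when the readxl package is installed),
#' optionally renaming source columns to the package's column dictionary via
#' `column_map`, and validates records: genotype must be AA/AG/GG, arm
#' drug/placebo, and volumes/percentages non-negative. Invalid rows are
#' excluded with a message; the exclusion count is attached as the
#' `n_excluded` attribute.
#'
#' @param path CSV or XLSX file.
#' @param column_map Named character vector or list mapping canonical column
#'   names to source column names, e.g. `c(genotype = "rs1535_gt")`; can
#'   also be the path to a JSON file holding such a map.
#' @return A validated cohort data frame with attribute `n_excluded`.
#' @export
ingest_cohort <- function(path, column_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }

  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map))
    column_map <- jsonlite::read_json(column_map, simplifyVector = TRUE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src))
      stop(sprintf("mapped source columns absent from file: %s",
                   paste(missing_src, collapse = ", ")), call. = FALSE)
    names(df)[match(unname(column_map), names(df))] <- names(column_map)
  }

  gaps <- setdiff(required_cohort_columns, names(df))
  if (length(gaps))
    stop(sprintf("cohort file lacks required columns: %s",
                 paste(gaps, collapse = ", ")), call. = FALSE)

  bad <- !(df$genotype %in% c("AA", "AG", "GG")) |
    !(df$arm %in% c("drug", "placebo"))
  nonneg <- grep("^(lvesvi|lvedvi|ecv_noninfarct|lvef|epa|dha|o3i)_",
                 names(df), value = TRUE)
  for (v in nonneg) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    df[[v]] <- x
    bad <- bad | (!is.na(x) & x < 0)
  }
  if (any(bad))
    message(sprintf("ingest_cohort: excluded %d invalid record(s)",
                    sum(bad)))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(bad)
  out
}
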