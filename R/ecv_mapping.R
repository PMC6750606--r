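#' Longitudinal relaxation rate R1
#'
#' R1 is the reciprocal of the longitudinal relaxation time, `1 / T1`.
#'
#' @param t1 T1 in seconds, strictly positive (vectorised).
#' @return R1 in s^-1.
#' @examples
#' compute_r1(1.0)   # 1
#' compute_r1(0.25)  # 4
#' @export
compute_r1 <- function(t1) {
  stopifnot(is.numeric(t1))
  if (any(!is.finite(t1)) || any(t1 <= 0))
    stop("t1 must be finite and strictly positive", call. = FALSE)
  1 / t1
}

#' Blood/myocardium R1 pairs
#'
#' @param r1_blood,r1_myo Positive relaxation rates in s^-1 (vectorised).
#' @param timepoint Optional labels (e.g. `"pre"`, `"5min"`).
#' @return A data frame of class `r1_pairs`.
#' @export
r1_pairs <- function(r1_blood, r1_myo, timepoint = NULL) {
  stopifnot(length(r1_blood) == length(r1_myo))
  if (any(!is.finite(r1_blood)) || any(!is.finite(r1_myo)) ||
      any(r1_blood <= 0) || any(r1_myo <= 0))
    stop("R1 values must be finite and positive", call. = FALSE)
  if (is.null(timepoint)) timepoint <- as.character(seq_along(r1_blood))
  out <- data.frame(r1_blood = as.numeric(r1_blood),
                    r1_myo = as.numeric(r1_myo),
                    timepoint = as.character(timepoint),
                    stringsAsFactors = FALSE)
  class(out) <- c("r1_pairs", "data.frame")
  out
}

#' Estimate the contrast partition coefficient
#'
#' Ordinary least-squares regression of myocardial R1 on blood-pool R1 across
#' contrast states; the slope is the partition coefficient lambda. Pairs whose
#' blood-pool R1 is not below `r1_blood_max` (default 3.5 s^-1) are excluded
#' before fitting, because fast-water-exchange conditions may not hold at high
#' blood gadolinium concentration and retaining them underestimates ECV.
#'
#' @param pairs A data frame with columns `r1_blood`, `r1_myo` (see
#'   [r1_pairs()]).
#' @param r1_blood_max Exclusion boundary in s^-1; pairs with
#'   `r1_blood >= r1_blood_max` are excluded.
#' @return A list of class `partition_fit`: `lambda` (slope), `intercept`
#'   (s^-1), `n_used`, `excluded` (data frame of dropped pairs), `model`
#'   (the underlying `lm` fit).
#' @examples
#' p <- r1_pairs(c(0.6, 1.5, 2.5, 3.2), 0.30 * c(0.6, 1.5, 2.5, 3.2) + 0.2)
#' fit_partition_coefficient(p)$lambda  # 0.30
#' @export
fit_partition_coefficient <- function(pairs, r1_blood_max = 3.5) {
  if (!all(c("r1_blood", "r1_myo") %in% names(pairs)))
    stop("pairs must have columns r1_blood and r1_myo", call. = FALSE)
  drop <- pairs$r1_blood >= r1_blood_max
  kept <- pairs[!drop, , drop = FALSE]
  if (nrow(kept) < 2L)
    stop(sprintf(
      "fewer than 2 R1 pairs remain after excluding blood R1 >= %.3g s^-1",
      r1_blood_max), call. = FALSE)
  fit <- stats::lm(r1_myo ~ r1_blood, data = kept)
  co <- stats::coef(fit)
  structure(
    list(lambda = unname(co[["r1_blood"]]),
         intercept = unname(co[["(Intercept)"]]),
         n_used = nrow(kept),
         excluded = pairs[drop, , drop = FALSE],
         model = fit),
    class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("<partition_fit: lambda=%.4f intercept=%.4f s^-1 n=%d (%d excluded)>\n",
              x$lambda, x$intercept, x$n_used, nrow(x$excluded)))
  invisible(x)
}

#' Extracellular volume fraction from lambda and hematocrit
#'
#' `ECV = lambda * (1 - HCT)`. A result outside `[0, 1]` is non-physical;
#' it is returned unchanged with a warning rather than clipped.
#'
#' @param lambda_ Partition coefficient (dimensionless slope).
#' @param hct Hematocrit as a fraction strictly inside (0, 1).
#' @return ECV as a fraction.
#' @examples
#' compute_ecv(0.45, 0.40)  # 0.27
#' @export
compute_ecv <- function(lambda_, hct) {
  stopifnot(is.numeric(lambda_), is.numeric(hct))
  if (any(hct <= 0) || any(hct >= 1))
    stop("hematocrit must lie strictly inside (0, 1)", call. = FALSE)
  ecv <- lambda_ * (1 - hct)
  if (any(ecv < 0 | ecv > 1))
    warning("non-physical ECV outside [0, 1]; value returned unclipped",
            call. = FALSE)
  ecv
}

#' One-call ECV estimation from R1 pairs
#'
#' Convenience wrapper: [fit_partition_coefficient()] followed by
#' [compute_ecv()], keeping the exclusion bookkeeping.
#'
#' @inheritParams fit_partition_coefficient
#' @inheritParams compute_ecv
#' @return A list of class `ecv_fit`: `lambda`, `intercept`, `ecv`, `hct`,
#'   `n_used`, `excluded`.
#' @export
estimate_ecv <- function(pairs, hct, r1_blood_max = 3.5) {
  pf <- fit_partition_coefficient(pairs, r1_blood_max = r1_blood_max)
  ecv <- compute_ecv(pf$lambda, hct)
  structure(
    list(lambda = pf$lambda, intercept = pf$intercept, ecv = ecv, hct = hct,
         n_used = pf$n_used, excluded = pf$excluded),
    class = "ecv_fit")
}

#' @export
print.ecv_fit <- function(x, ...) {
  cat(sprintf("<ecv_fit: lambda=%.4f ECV=%.3f (HCT=%.3f, n=%d, %d excluded)>\n",
              x$lambda, x$ecv, x$hct, x$n_used, nrow(x$excluded)))
  invisible(x)
}

#' Segmental ECV map (AHA 16-segment model)
#'
#' @param segment_ids Segment labels (length 16 for the full AHA model, but
#'   any non-empty set is accepted).
#' @param ecv_values ECV fractions in `[0, 1]`, same length.
#' @param lge_positive Logical flags marking segments with matching late
#'   gadolinium enhancement.
#' @return A data frame of class `segmental_ecv_map`.
#' @export
segmental_ecv_map <- function(segment_ids, ecv_values, lge_positive) {
  if (length(segment_ids) != length(ecv_values) ||
      length(segment_ids) != length(lge_positive))
    stop("segment_ids, ecv_values and lge_positive must have equal length",
         call. = FALSE)
  if (any(!is.finite(ecv_values)) || any(ecv_values < 0 | ecv_values > 1))
    stop("ecv_values must be fractions in [0, 1]", call. = FALSE)
  out <- data.frame(segment_id = as.character(segment_ids),
                    ecv = as.numeric(ecv_values),
                    lge_positive = as.logical(lge_positive),
                    stringsAsFactors = FALSE)
  class(out) <- c("segmental_ecv_map", "data.frame")
  out
}

#' Global non-infarct ECV
#'
#' Unweighted mean ECV over segments without matching late enhancement; this
#' is the ECV_Non-Infarct estimate of diffuse (non-infarct) fibrosis.
#'
#' @param map A [segmental_ecv_map()].
#' @return A fraction.
#' @examples
#' m <- segmental_ecv_map(c("s1", "s2"), c(0.30, 0.40), c(FALSE, TRUE))
#' aggregate_noninfarct_ecv(m)  # 0.30
#' @export
aggregate_noninfarct_ecv <- function(map) {
  if (!all(c("ecv", "lge_positive") %in% names(map)))
    stop("map must have columns ecv and lge_positive", call. = FALSE)
  remote <- map$ecv[!map$lge_positive]
  if (length(remote) == 0L)
    stop("all segments are LGE-positive: no remote myocardium to average",
         call. = FALSE)
  mean(remote)
}
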