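#' Omega-3 index
#'
#' The omega-3 index (O3I) is the sum of eicosapentaenoic acid (EPA) and
#' docosahexaenoic acid (DHA), each expressed as a percentage of total red
#' blood cell fatty acids.
#'
#' @param epa_pct,dha_pct EPA and DHA as percentages in `[0, 100]`
#'   (vectorised).
#' @return O3I in percent.
#' @examples
#' omega3_index(2.1, 4.3)  # 6.4
#' @export
omega3_index <- function(epa_pct, dha_pct) {
  stopifnot(is.numeric(epa_pct), is.numeric(dha_pct))
  if (any(epa_pct < 0, na.rm = TRUE) || any(dha_pct < 0, na.rm = TRUE))
    stop("fatty-acid percentages must be non-negative", call. = FALSE)
  if (any(epa_pct + dha_pct > 100, na.rm = TRUE))
    stop("EPA + DHA cannot exceed 100% of total fatty acids", call. = FALSE)
  epa_pct + dha_pct
}

#' Desaturase-activity surrogate (ArA/LA ratio)
#'
#' FADS2 (delta-6 desaturase) activity is estimated by the product/precursor
#' ratio of arachidonic acid to linoleic acid in the red-cell membrane.
#' Carriers of the rs1535 minor G allele desaturate less, so ArA/LA falls
#' with the number of G alleles.
#'
#' @param ara_pct,la_pct ArA and LA as percentages of total RBC fatty acids;
#'   `la_pct` must be positive (vectorised).
#' @return The dimensionless ArA/LA ratio.
#' @examples
#' fads2_activity(16, 10)  # 1.6
#' @export
fads2_activity <- function(ara_pct, la_pct) {
  stopifnot(is.numeric(ara_pct), is.numeric(la_pct))
  if (any(ara_pct < 0, na.rm = TRUE))
    stop("ArA percentage must be non-negative", call. = FALSE)
  if (any(la_pct <= 0, na.rm = TRUE))
    stop("LA percentage must be strictly positive", call. = FALSE)
  ara_pct / la_pct
}

#' Genotype count table for a biallelic SNP
#'
#' Counts of the three rs1535 genotypes, with A the major and G the minor
#' allele.
#'
#' @param n_aa,n_ag,n_gg Non-negative integer counts; total must be positive.
#' @return An object of class `genotype_table`.
#' @examples
#' genotype_table(156, 122, 34)
#' @export
genotype_table <- function(n_aa, n_ag, n_gg) {
  counts <- c(n_aa = n_aa, n_ag = n_ag, n_gg = n_gg)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("genotype table is empty", call. = FALSE)
  structure(as.list(counts), total = sum(counts), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  n <- attr(x, "total")
  cat(sprintf("<genotype_table: AA=%d (%.0f%%) AG=%d (%.0f%%) GG=%d (%.0f%%), n=%d>\n",
              x$n_aa, 100 * x$n_aa / n, x$n_ag, 100 * x$n_ag / n,
              x$n_gg, 100 * x$n_gg / n, n))
  invisible(x)
}

#' Allele frequencies from genotype counts
#'
#' @param table A [genotype_table()].
#' @return Named numeric vector `c(freq_A=, freq_G=)`, summing to 1.
#' @examples
#' allele_frequencies(genotype_table(156, 122, 34))  # freq_G = 190/624
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  n <- attr(table, "total")
  freq_a <- (2 * table$n_aa + table$n_ag) / (2 * n)
  c(freq_A = freq_a, freq_G = 1 - freq_a)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom asymptotic chi-square comparing observed genotype
#' counts to the Hardy-Weinberg expectations `n p^2`, `2 n p q`, `n q^2`
#' computed from the observed allele frequencies.
#'
#' @param table A [genotype_table()] with total count >= 5.
#' @return A list of class `hwe_test`: `statistic`, `df` (1), `p_value`,
#'   `observed`, `expected`, and `small_expected` (TRUE when any expected
#'   cell is below 1, in which case the asymptotic p-value is unreliable and
#'   a warning is raised).
#' @examples
#' hwe_chi_square(genotype_table(156, 122, 34))
#' @export
hwe_chi_square <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  n <- attr(table, "total")
  if (n < 5)
    stop("at least 5 genotyped individuals are required", call. = FALSE)
  p <- allele_frequencies(table)[["freq_A"]]
  q <- 1 - p
  observed <- c(AA = table$n_aa, AG = table$n_ag, GG = table$n_gg)
  expected <- c(AA = n * p^2, AG = 2 * n * p * q, GG = n * q^2)
  # a monomorphic sample has structurally-zero expected cells that carry no
  # information; they contribute nothing to the statistic
  use <- expected > 0
  statistic <- sum((observed[use] - expected[use])^2 / expected[use])
  small <- any(expected[use] < 1)
  if (small)
    warning("expected genotype count below 1; asymptotic p-value unreliable",
            call. = FALSE)
  structure(
    list(statistic = statistic, df = 1L,
         p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
         observed = observed, expected = expected,
         small_expected = small),
    class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("<hwe_test: chi-square=%.3f df=1 p=%.3g>\n",
              x$statistic, x$p_value))
  invisible(x)
}
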