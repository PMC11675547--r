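# Maximum-tolerated allele-count test underlying BA1/BS1/PM2.
#
# An allele frequency threshold is converted into the largest allele count
# still compatible with that frequency at a given one-sided confidence level,
# under a Poisson model for the sampling of allele counts (the convention of
# the CardioDB allele-frequency application).  A variant "exceeds" a
# frequency threshold only when its observed count is strictly above the
# tolerated count.

#' Frequency thresholds for population evidence
#'
#' Container for the maximum-tolerated allele-frequency thresholds used by
#' the population criteria: BA1 (stand-alone benign) at 0.001 and BS1
#' (strong benign) at 0.0001, evaluated at a one-sided 95% confidence level
#' against gnomAD non-cancer female popmax counts.
#'
#' @param ba1_af BA1 allele-frequency threshold (default `0.001`).
#' @param bs1_af BS1 allele-frequency threshold (default `0.0001`).
#' @param confidence One-sided confidence level in `(0, 1)` (default `0.95`).
#' @return A list of class `vc_freq_thresholds`.
#' @examples
#' frequency_thresholds()
#' @export
frequency_thresholds <- function(ba1_af = 0.001, bs1_af = 0.0001,
                                 confidence = 0.95) {
  stopifnot(is.finite(ba1_af), is.finite(bs1_af), is.finite(confidence))
  if (!(ba1_af > bs1_af && bs1_af > 0))
    stop("need ba1_af > bs1_af > 0", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
  structure(list(ba1_af = ba1_af, bs1_af = bs1_af, confidence = confidence),
            class = "vc_freq_thresholds")
}

#' Maximum tolerated allele count at a frequency threshold
#'
#' Returns the largest allele count still compatible with a population
#' allele frequency `af_threshold` given `allele_number` genotyped alleles:
#' the `confidence`-level quantile of a Poisson distribution with mean
#' `af_threshold * allele_number` (the Poisson approximation to binomial
#' allele-count sampling).  Counts strictly above this value reject the
#' frequency hypothesis at the one-sided level.
#'
#' @param af_threshold Allele-frequency threshold in `(0, 1)`.
#' @param allele_number Number of alleles genotyped (positive integer).
#' @param confidence One-sided confidence level in `(0, 1)` (default 0.95).
#' @return Non-negative integer tolerated count.
#' @examples
#' max_tolerated_allele_count(0.0001, 100000)   # Poisson(10) 95% quantile
#' @export
max_tolerated_allele_count <- function(af_threshold, allele_number,
                                       confidence = 0.95) {
  if (!is.finite(af_threshold) || af_threshold <= 0 || af_threshold >= 1)
    stop("af_threshold must be a finite fraction in (0, 1)", call. = FALSE)
  if (!is.finite(allele_number) || allele_number < 1)
    stop("allele_number must be a positive integer", call. = FALSE)
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
  as.integer(stats::qpois(confidence, lambda = af_threshold * allele_number))
}

#' Does an observed allele count exceed a frequency threshold?
#'
#' Strict comparison against [max_tolerated_allele_count()]: `TRUE` only when
#' the observed count is strictly greater than the tolerated count.  Absent
#' counts yield `NA` ("insufficient data"), which the engines route to the
#' PM2 path, never to BA1/BS1.
#'
#' @param allele_count Observed allele count, or `NA`.
#' @param allele_number Alleles genotyped, or `NA`.
#' @param af_threshold Frequency threshold to test against.
#' @param confidence One-sided confidence level (default 0.95).
#' @return `TRUE`, `FALSE`, or `NA` when counts are absent.
#' @examples
#' exceeds_frequency_threshold(16, 100000, 0.0001)  # tolerance is 15
#' @export
exceeds_frequency_threshold <- function(allele_count, allele_number,
                                        af_threshold, confidence = 0.95) {
  if (is.na(allele_count) || is.na(allele_number)) return(NA)
  if (allele_count > allele_number)
    stop("allele_count exceeds allele_number", call. = FALSE)
  allele_count > max_tolerated_allele_count(af_threshold, allele_number,
                                            confidence)
}
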