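# Pairwise engine comparison: 3x3 confusion matrix, exact-binomial
# concordance, per-tier distributions, submitter-stratified agreement and
# consensus-update comparison.

#' Round a percentage to one decimal, half away from zero
#'
#' The rounding convention used for all printed percentages in the
#' package's reports.
#'
#' @param count Numerator count (vectorised).
#' @param n Denominator.
#' @return Percentage rounded to one decimal place.
#' @examples
#' percent_of(232, 450)   # 51.6
#' @export
percent_of <- function(count, n) {
  p <- 100 * count / n
  sign(p) * floor(abs(p) * 10 + 0.5 + 1e-9) / 10
}

#' Build a 3x3 tier confusion matrix
#'
#' Cross-tabulates two aligned vectors of consolidated tiers in the fixed
#' order `P_LP`, `VUS`, `B_LB` (rows = first engine, columns = second).
#'
#' @param a,b Character vectors of [vc_tiers3()] labels, aligned by variant.
#' @param labels Optional dimension names (default `c("A", "B")`).
#' @return A `vc_confusion` matrix with `row_totals`, `col_totals` and
#'   `grand_total` attributes.
#' @examples
#' build_confusion(c("P_LP", "VUS"), c("P_LP", "B_LB"))
#' @export
build_confusion <- function(a, b, labels = c("A", "B")) {
  if (length(a) != length(b))
    stop("tier vectors are not aligned: ", length(a), " vs ", length(b),
         call. = FALSE)
  fa <- factor(a, levels = vc_tiers3())
  fb <- factor(b, levels = vc_tiers3())
  if (anyNA(fa) || anyNA(fb))
    stop("unknown tier label(s) in input", call. = FALSE)
  m <- table(fa, fb)
  m <- matrix(as.integer(m), nrow = 3, dimnames = list(vc_tiers3(), vc_tiers3()))
  names(dimnames(m)) <- labels
  structure(m, class = c("vc_confusion", "matrix"),
            row_totals = rowSums(m), col_totals = colSums(m),
            grand_total = sum(m))
}

#' @export
print.vc_confusion <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  disp <- cbind(m, total = rowSums(m))
  disp <- rbind(disp, total = colSums(disp))
  print(disp)
  invisible(x)
}

#' Plot a tier confusion matrix as a plain heatmap
#'
#' @param x A `vc_confusion` matrix.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.vc_confusion <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  graphics::image(seq_len(3), seq_len(3), t(m[3:1, ]), axes = FALSE,
                  xlab = names(dimnames(m))[2], ylab = names(dimnames(m))[1],
                  col = grDevices::hcl.colors(24, "Blues", rev = TRUE), ...)
  graphics::axis(1, at = 1:3, labels = colnames(m))
  graphics::axis(2, at = 3:1, labels = rownames(m))
  for (i in 1:3) for (j in 1:3)
    graphics::text(j, 4 - i, m[i, j])
  graphics::box()
  invisible(x)
}

#' Concordance rate with an exact binomial confidence interval
#'
#' Overall agreement (matrix trace over grand total) with an exact
#' Clopper-Pearson interval at the stated confidence level.
#'
#' @param m A `vc_confusion` matrix.
#' @param confidence Two-sided confidence level (default 0.95).
#' @return A `vc_agreement` list: `matrix`, `concordance`, `ci_low`,
#'   `ci_high`, `n`, `concordant`.
#' @examples
#' m <- build_confusion(rep("VUS", 4), c("VUS", "VUS", "VUS", "B_LB"))
#' concordance_rate(m)
#' @export
concordance_rate <- function(m, confidence = 0.95) {
  stopifnot(inherits(m, "vc_confusion"))
  n <- attr(m, "grand_total")
  if (n < 1L) stop("empty confusion matrix", call. = FALSE)
  tr <- sum(diag(unclass(m)))
  ci <- stats::binom.test(tr, n, conf.level = confidence)$conf.int
  structure(
    list(matrix = m, concordance = tr / n, concordant = tr, n = n,
         ci_low = ci[1L], ci_high = ci[2L], confidence = confidence),
    class = "vc_agreement"
  )
}

#' @export
print.vc_agreement <- function(x, ...) {
  cat(sprintf("Concordance: %.1f%% (%d/%d), %g%% CI %.1f-%.1f%%\n",
              100 * x$concordance, x$concordant, x$n, 100 * x$confidence,
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Per-tier counts and percentages of a set of classifications
#'
#' Consolidates engine classifications to the three tiers and reports
#' counts plus percentages rounded to one decimal (half away from zero).
#'
#' @param results A list of `vc_classification` objects, or a character
#'   vector of five- or three-tier labels.
#' @return Data frame with columns `tier`, `count`, `percent`.
#' @examples
#' classification_distribution(c(rep("P_LP", 51), rep("VUS", 111),
#'                               rep("B_LB", 288)))
#' @export
classification_distribution <- function(results) {
  tiers <- as_tiers(results)
  if (!length(tiers)) stop("no classifications supplied", call. = FALSE)
  counts <- table(factor(tiers, levels = vc_tiers3()))
  data.frame(
    tier = vc_tiers3(),
    count = as.integer(counts),
    percent = percent_of(as.integer(counts), length(tiers)),
    stringsAsFactors = FALSE
  )
}

as_tiers <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1L]], "vc_classification"))
    x <- vapply(x, function(r) r$category, character(1))
  x <- as.character(x)
  ifelse(x %in% vc_tiers3(), x, consolidate(x))
}

#' Agreement stratified by submitter composition
#'
#' For a focal tier, groups variants into three strata of ClinVar submitter
#' support — more than 50% of countable submitters asserting the tier, 50%
#' or fewer (but at least one), and at least one (the union) — and reports,
#' per stratum, how many variants the engine places in that same tier.
#'
#' @param classifications List of `vc_classification` objects or tier
#'   labels, aligned with `sets`.
#' @param sets List of `vc_submission_set` objects.
#' @param tier Focal tier, one of [vc_tiers3()].
#' @return Data frame with columns `stratum`, `n`, `matches`, `percent`
#'   (`percent` is `NA` for an empty stratum).
#' @export
stratified_agreement <- function(classifications, sets, tier) {
  tier <- match.arg(tier, vc_tiers3())
  tiers <- as_tiers(classifications)
  if (length(tiers) != length(sets))
    stop("classifications and submission sets are not aligned", call. = FALSE)
  frac <- vapply(sets, submitter_tier_fraction, numeric(1), tier = tier)
  in_majority <- frac > 0.5
  in_minority <- frac <= 0.5 & frac > 0
  any_sub <- frac > 0
  one <- function(name, sel) {
    n <- sum(sel)
    matches <- sum(sel & tiers == tier)
    data.frame(stratum = name, n = n, matches = matches,
               percent = if (n) percent_of(matches, n) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one("majority", in_majority),
        one("minority", in_minority),
        one("any", any_sub))
}

#' Compare engine classifications with later consensus classifications
#'
#' Restricts to variants whose later ClinVar snapshot reached a consensus,
#' tallies the consensus tiers, and lists every variant where the engine's
#' consolidated tier disagrees with the consensus tier.
#'
#' @param engine_results List of `vc_classification` objects or tier
#'   labels, aligned with `consensus_tiers`.
#' @param consensus_tiers Character vector of [vc_tiers3()] labels with
#'   `NA` for variants that did not reach consensus (e.g. from
#'   [detect_consensus()]).
#' @param variant_ids Optional identifiers used in the mismatch listing.
#' @return A list: `n_total`, `n_consensus`, `consensus_fraction_percent`,
#'   `tier_counts` (named P_LP/VUS/B_LB), and `mismatches` (data frame of
#'   `variant_id`, `engine_tier`, `consensus_tier`).
#' @export
consensus_comparison <- function(engine_results, consensus_tiers,
                                 variant_ids = NULL) {
  tiers <- as_tiers(engine_results)
  if (length(tiers) != length(consensus_tiers))
    stop("engine results and consensus tiers are not aligned", call. = FALSE)
  if (is.null(variant_ids)) variant_ids <- as.character(seq_along(tiers))
  has <- !is.na(consensus_tiers)
  cons <- consensus_tiers[has]
  eng <- tiers[has]
  ids <- variant_ids[has]
  counts <- table(factor(cons, levels = vc_tiers3()))
  mism <- which(eng != cons)
  list(
    n_total = length(tiers),
    n_consensus = sum(has),
    consensus_fraction_percent = percent_of(sum(has), length(tiers)),
    tier_counts = stats::setNames(as.integer(counts), vc_tiers3()),
    mismatches = data.frame(variant_id = ids[mism],
                            engine_tier = eng[mism],
                            consensus_tier = cons[mism],
                            stringsAsFactors = FALSE)
  )
}
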