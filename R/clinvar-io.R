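# Ingest of ClinVar-style per-submission tables: label normalisation,
# grouping into per-variant submission sets, conflict selection, submitter
# tallies and later-snapshot consensus detection.
#
# The dialect is a simplified variant_summary-like TSV defined by this
# package (UTF-8, tab-delimited, header required):
#   variant_id gene hgvs_c hgvs_p protein_position consequence
#   submitter_id classification assertion_criteria snapshot_date

submission_columns <- function() {
  c("variant_id", "gene", "hgvs_c", "hgvs_p", "protein_position",
    "consequence", "submitter_id", "classification", "assertion_criteria",
    "snapshot_date")
}

#' Normalise free-text classification labels to the five tiers
#'
#' Case-insensitive mapping of common ClinVar spellings ("Pathogenic",
#' "likely benign", "Uncertain significance", ...) and the coded labels
#' themselves onto `PV`, `LPV`, `VUS`, `LBV`, `BV`.  Unrecognised labels
#' map to `NA`.
#'
#' @param x Character vector of labels.
#' @return Character vector of five-tier labels or `NA`.
#' @examples
#' normalize_classification(c("Pathogenic", "likely benign", "VUS"))
#' @export
normalize_classification <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[_-]", " ", key)
  map <- c(
    "pathogenic" = "PV", "pv" = "PV",
    "likely pathogenic" = "LPV", "lpv" = "LPV", "lp" = "LPV",
    "uncertain significance" = "VUS", "vus" = "VUS",
    "variant of uncertain significance" = "VUS",
    "likely benign" = "LBV", "lbv" = "LBV", "lb" = "LBV",
    "benign" = "BV", "bv" = "BV"
  )
  unname(map[key])
}

#' Parse a ClinVar-style submission table
#'
#' Reads the tab-delimited per-submission dialect (header required; see
#' package vignette), normalises classification labels, validates rows, and
#' groups submissions into per-variant sets.  Malformed rows (unknown
#' classification, missing position, bad consequence) are dropped and
#' reported with their line numbers in the `errors` attribute.
#'
#' @param path Path to a TSV file.
#' @return A list of `vc_submission_set` objects (one per variant, input
#'   order preserved), with attribute `errors`: a data frame of
#'   `line`/`variant_id`/`problem` for rejected rows.
#' @export
parse_submission_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(submission_columns(), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  errors <- data.frame(line = integer(), variant_id = character(),
                       problem = character(), stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    out <- list()
    attr(out, "errors") <- errors
    return(out)
  }
  raw$.line <- seq_len(nrow(raw)) + 1L   # header is line 1
  raw$classification <- normalize_classification(raw$classification)
  raw$protein_position <- suppressWarnings(as.integer(raw$protein_position))
  raw$assertion_criteria <- tolower(raw$assertion_criteria) %in%
    c("true", "t", "1", "yes")
  bad <- is.na(raw$classification)
  reject <- function(idx, why) {
    if (any(idx))
      errors <<- rbind(errors, data.frame(
        line = raw$.line[idx], variant_id = raw$variant_id[idx],
        problem = why, stringsAsFactors = FALSE))
  }
  reject(bad, "unknown classification label")
  badpos <- !bad & (is.na(raw$protein_position) | raw$protein_position < 1L)
  reject(badpos, "invalid protein_position")
  badcons <- !bad & !badpos & !raw$consequence %in% c("missense", "other")
  reject(badcons, "invalid consequence")
  keep <- raw[!(bad | badpos | badcons), , drop = FALSE]
  sets <- list()
  for (vid in unique(keep$variant_id)) {
    rows <- keep[keep$variant_id == vid, , drop = FALSE]
    v <- variant_record(vid, gene = rows$gene[1L], hgvs_c = rows$hgvs_c[1L],
                        hgvs_p = rows$hgvs_p[1L],
                        protein_position = rows$protein_position[1L],
                        consequence = rows$consequence[1L])
    subs <- rows[, c("submitter_id", "classification", "assertion_criteria",
                     "snapshot_date")]
    rownames(subs) <- NULL
    sets[[length(sets) + 1L]] <- structure(
      list(variant = v, submissions = subs), class = "vc_submission_set")
  }
  attr(sets, "errors") <- errors
  sets
}

#' @export
print.vc_submission_set <- function(x, ...) {
  tab <- table(x$submissions$classification)
  cat(sprintf("<submission set %s> %d submission(s): %s\n",
              x$variant$variant_id, nrow(x$submissions),
              paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

countable <- function(set) {
  set$submissions[set$submissions$assertion_criteria, , drop = FALSE]
}

#' Is a submission set in conflict?
#'
#' A variant has conflicting interpretations when at least two
#' assertion-criteria submissions map to at least two distinct consolidated
#' tiers.  Disagreement within a tier (PV vs LPV) is not a conflict.
#'
#' @param set A `vc_submission_set`.
#' @return `TRUE` or `FALSE`.
#' @export
is_conflicting <- function(set) {
  sub <- countable(set)
  nrow(sub) >= 2L && length(unique(consolidate(sub$classification))) >= 2L
}

#' Select conflicting missense variants
#'
#' Filters parsed submission sets to those with `consequence = "missense"`
#' and [is_conflicting()] true, preserving input order.  Idempotent.
#'
#' @param sets List of `vc_submission_set` objects.
#' @return Filtered list.
#' @export
select_conflicting_missense <- function(sets) {
  keep <- vapply(sets, function(s)
    s$variant$consequence == "missense" && is_conflicting(s), logical(1))
  sets[keep]
}

#' Fraction of countable submitters asserting a tier
#'
#' Among assertion-criteria submissions only, the fraction whose
#' classification consolidates to the given tier.
#'
#' @param set A `vc_submission_set`.
#' @param tier One of [vc_tiers3()].
#' @return A fraction in `[0, 1]`.
#' @export
submitter_tier_fraction <- function(set, tier) {
  tier <- match.arg(tier, vc_tiers3())
  sub <- countable(set)
  if (nrow(sub) == 0L)
    stop("no countable (assertion-criteria) submissions for variant ",
         set$variant$variant_id, call. = FALSE)
  mean(consolidate(sub$classification) == tier)
}

#' Detect a consensus classification in a later snapshot
#'
#' Returns the single consolidated tier when every assertion-criteria
#' submission agrees at the three-tier level, and `NA` when the set is
#' still conflicting.
#'
#' @param set A later-snapshot `vc_submission_set`.
#' @return One of [vc_tiers3()], or `NA_character_`.
#' @export
detect_consensus <- function(set) {
  sub <- countable(set)
  if (nrow(sub) == 0L)
    stop("no countable (assertion-criteria) submissions for variant ",
         set$variant$variant_id, call. = FALSE)
  tiers <- unique(consolidate(sub$classification))
  if (length(tiers) == 1L) tiers else NA_character_
}
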