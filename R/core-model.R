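# Core domain model: evidence codes, strengths, five- and three-tier labels,
# and the classed objects shared by both classification engines.

#' Evidence codes, strengths and classification tiers
#'
#' Closed vocabularies used throughout the package.  `vc_codes()` lists the
#' ACMG/AMP evidence codes the engines can emit, `vc_strengths()` the graded
#' evidence strengths, `vc_tiers5()` the five-tier pathogenicity labels and
#' `vc_tiers3()` the consolidated three-tier labels.
#'
#' @return A character vector of valid labels.
#' @examples
#' vc_codes()
#' vc_tiers3()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
vc_codes <- function() {
  c("PS1", "PS3", "PS4", "PM1", "PM2", "PM5", "PP3", "PP5",
    "BA1", "BS1", "BS3", "BP1", "BP3", "BP4", "BP6")
}

#' @rdname vocabularies
#' @export
vc_strengths <- function() {
  c("supporting", "moderate", "strong", "very_strong", "standalone")
}

#' @rdname vocabularies
#' @export
vc_tiers5 <- function() c("PV", "LPV", "VUS", "LBV", "BV")

#' @rdname vocabularies
#' @export
vc_tiers3 <- function() c("P_LP", "VUS", "B_LB")

# points per graded strength; standalone (BA1) carries the very-strong
# magnitude so totals stay well-defined, but the category comes from the
# standalone override, not the sum.
.strength_points <- c(
  supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L,
  standalone = 8L
)

.code_direction <- c(
  PS1 = "pathogenic", PS3 = "pathogenic", PS4 = "pathogenic",
  PM1 = "pathogenic", PM2 = "pathogenic", PM5 = "pathogenic",
  PP3 = "pathogenic", PP5 = "pathogenic",
  BA1 = "benign", BS1 = "benign", BS3 = "benign",
  BP1 = "benign", BP3 = "benign", BP4 = "benign", BP6 = "benign"
)

#' Construct one evidence assignment
#'
#' An evidence assignment is one triggered ACMG/AMP code at a given strength.
#' The direction (pathogenic or benign) is implied by the code, and the signed
#' point value follows the points-based convention: supporting 1, moderate 2,
#' strong 4, very strong 8, negated for benign-direction codes.  `BA1` is the
#' only code allowed (and required) to carry the `standalone` strength.
#'
#' @param code One of [vc_codes()].
#' @param strength One of [vc_strengths()].
#' @param note Optional free-text annotation kept with the assignment (used
#'   e.g. to retain the splice-effect flavour of PS3).
#' @return A one-row data frame with columns `code`, `direction`, `strength`,
#'   `points` and `note`.
#' @examples
#' evidence("PS3", "strong")
#' evidence("BP4", "supporting")
#' @export
evidence <- function(code, strength, note = NA_character_) {
  code <- match.arg(code, vc_codes())
  strength <- match.arg(strength, vc_strengths())
  if (code == "BA1" && strength != "standalone")
    stop("BA1 must be assigned at standalone strength", call. = FALSE)
  if (code != "BA1" && strength == "standalone")
    stop("standalone strength is reserved for BA1, got ", code, call. = FALSE)
  direction <- unname(.code_direction[code])
  pts <- unname(.strength_points[strength])
  if (direction == "benign") pts <- -pts
  data.frame(
    code = code, direction = direction, strength = strength,
    points = as.integer(pts), note = note,
    stringsAsFactors = FALSE
  )
}

#' Bind evidence assignments into one evidence table
#'
#' @param ... One-row evidence data frames from [evidence()], or `NULL`s
#'   (dropped), or lists of such rows.
#' @return A data frame with zero or more evidence rows.
#' @export
evidence_table <- function(...) {
  parts <- list(...)
  flat <- list()
  for (p in parts) {
    if (is.null(p)) next
    if (is.data.frame(p)) flat[[length(flat) + 1L]] <- p
    else if (is.list(p)) for (q in p) if (!is.null(q)) flat[[length(flat) + 1L]] <- q
  }
  if (!length(flat)) return(empty_evidence())
  do.call(rbind, flat)
}

empty_evidence <- function() {
  data.frame(
    code = character(), direction = character(), strength = character(),
    points = integer(), note = character(), stringsAsFactors = FALSE
  )
}

points_to_strength <- function(points) {
  m <- c(`1` = "supporting", `2` = "moderate", `4` = "strong",
         `8` = "very_strong")
  out <- m[as.character(abs(points))]
  if (anyNA(out)) stop("no graded strength for points ", points, call. = FALSE)
  unname(out)
}

#' Construct a variant record
#'
#' A protein-level description of one missense variant.  The engines operate
#' on protein annotations only; genomic coordinates and transcripts are out
#' of scope.
#'
#' @param variant_id Opaque identifier string.
#' @param gene Gene symbol (default `"BRCA1"`).
#' @param hgvs_c Coding-sequence HGVS string, e.g. `"c.5408G>C"`.
#' @param hgvs_p Protein HGVS string, e.g. `"p.Gly1803Ala"`.
#' @param protein_position 1-based amino-acid index (positive integer).
#' @param consequence `"missense"` or `"other"`; the engines reject
#'   non-missense inputs.
#' @return A list of class `vc_variant`.
#' @examples
#' variant_record("v1", hgvs_c = "c.5408G>C", hgvs_p = "p.Gly1803Ala",
#'                protein_position = 1803)
#' @export
variant_record <- function(variant_id, gene = "BRCA1", hgvs_c = NA_character_,
                           hgvs_p = NA_character_, protein_position,
                           consequence = "missense") {
  consequence <- match.arg(consequence, c("missense", "other"))
  protein_position <- as.integer(protein_position)
  if (is.na(protein_position) || protein_position < 1L)
    stop("protein_position must be a positive integer", call. = FALSE)
  structure(
    list(variant_id = as.character(variant_id), gene = gene,
         hgvs_c = hgvs_c, hgvs_p = hgvs_p,
         protein_position = protein_position, consequence = consequence),
    class = "vc_variant"
  )
}

#' @export
print.vc_variant <- function(x, ...) {
  cat(sprintf("<variant %s> %s %s (%s) pos %d [%s]\n",
              x$variant_id, x$gene,
              ifelse(is.na(x$hgvs_c), "c.?", x$hgvs_c),
              ifelse(is.na(x$hgvs_p), "p.?", x$hgvs_p),
              x$protein_position, x$consequence))
  invisible(x)
}

#' Reference variant at the same amino-acid residue
#'
#' Describes a previously classified missense change at the same residue as
#' the query variant, used for the PM5 criterion.
#'
#' @param hgvs_p Protein HGVS of the reference variant.
#' @param classification `"PV"` or `"LPV"`.
#' @param revel REVEL score of the reference variant in `[0, 1]`, or `NA`.
#' @param limited_reports Logical; `TRUE` if the reference classification
#'   rests on limited reports (downgrades PM5 to supporting for LPV refs).
#' @return A one-row data frame.
#' @export
same_residue_ref <- function(hgvs_p, classification, revel = NA_real_,
                             limited_reports = FALSE) {
  if (is.na(classification) || !classification %in% c("PV", "LPV"))
    stop("same-residue reference requires classification PV or LPV, got: ",
         classification, call. = FALSE)
  if (!is.na(revel) && (revel < 0 || revel > 1))
    stop("reference REVEL must lie in [0, 1]", call. = FALSE)
  data.frame(hgvs_p = hgvs_p, classification = classification,
             revel = revel, limited_reports = isTRUE(limited_reports),
             stringsAsFactors = FALSE)
}

#' Construct an annotation bundle
#'
#' All per-variant evidence inputs the engines consume.  Every field may be
#' absent (`NA` / `NULL`): absent data never triggers benign frequency
#' evidence and simply silences the corresponding criterion elsewhere.
#'
#' @param af gnomAD non-cancer female popmax allele frequency in `[0, 1]`.
#' @param allele_count Observed allele count (non-negative integer).
#' @param allele_number Total alleles genotyped (positive integer).
#' @param revel REVEL ensemble missense score in `[0, 1]`.
#' @param metarnn MetaRNN missense score in `[0, 1]` (auto engine input).
#' @param splice_score Predicted splice-impact score in `[0, 1]`.
#' @param functional_result One of `"abnormal"`, `"normal"`,
#'   `"intermediate"`, `"splice_effect"`, `"none"`.
#' @param assay_strength Strength grade of the functional assay
#'   (`"strong"`, `"moderate"`, `"supporting"`), required when the result is
#'   abnormal, normal or splice_effect.
#' @param multifactorial_lr Published multifactorial likelihood ratio toward
#'   pathogenicity (positive; values `< 1` favour benignity).
#' @param case_control_or Case-control odds ratio (positive).
#' @param same_residue_refs Data frame of [same_residue_ref()] rows (may have
#'   zero rows).
#' @param same_aa_pathogenic Logical; `TRUE` asserts an identical amino-acid
#'   change already classified pathogenic (triggers PS1 at strong).
#' @param repeat_region Logical; `TRUE` marks the residue as lying in a
#'   repetitive region without known function (auto-engine BP3 emulation).
#' @return A list of class `vc_bundle`.
#' @examples
#' annotation_bundle(allele_count = 0, revel = 0.85,
#'                   functional_result = "abnormal", assay_strength = "strong")
#' @export
annotation_bundle <- function(af = NA_real_, allele_count = NA_integer_,
                              allele_number = NA_integer_, revel = NA_real_,
                              metarnn = NA_real_, splice_score = NA_real_,
                              functional_result = "none",
                              assay_strength = NA_character_,
                              multifactorial_lr = NA_real_,
                              case_control_or = NA_real_,
                              same_residue_refs = NULL,
                              same_aa_pathogenic = FALSE,
                              repeat_region = FALSE) {
  functional_result <- match.arg(
    functional_result,
    c("none", "abnormal", "normal", "intermediate", "splice_effect"))
  for (nm in c("af", "revel", "metarnn", "splice_score")) {
    v <- get(nm)
    if (!is.na(v) && (v < 0 || v > 1))
      stop(nm, " must lie in [0, 1], got ", v, call. = FALSE)
  }
  allele_count <- if (is.null(allele_count)) NA_integer_ else as.integer(allele_count)
  allele_number <- if (is.null(allele_number)) NA_integer_ else as.integer(allele_number)
  if (!is.na(allele_count) && allele_count < 0L)
    stop("allele_count must be non-negative", call. = FALSE)
  if (!is.na(allele_number) && allele_number < 1L)
    stop("allele_number must be positive", call. = FALSE)
  if (!is.na(allele_count) && !is.na(allele_number) &&
      allele_count > allele_number)
    stop("allele_count exceeds allele_number", call. = FALSE)
  if (!is.na(assay_strength))
    assay_strength <- match.arg(assay_strength,
                                c("strong", "moderate", "supporting"))
  if (is.null(same_residue_refs))
    same_residue_refs <- same_residue_ref("p.?", "PV")[0, ]
  structure(
    list(af = af, allele_count = allele_count, allele_number = allele_number,
         revel = revel, metarnn = metarnn, splice_score = splice_score,
         functional_result = functional_result,
         assay_strength = assay_strength,
         multifactorial_lr = multifactorial_lr,
         case_control_or = case_control_or,
         same_residue_refs = same_residue_refs,
         same_aa_pathogenic = isTRUE(same_aa_pathogenic),
         repeat_region = isTRUE(repeat_region)),
    class = "vc_bundle"
  )
}

#' Consolidate five-tier classifications into three broad tiers
#'
#' Maps the five pathogenicity tiers onto the three broad categories used for
#' all concordance and consensus analyses: PV and LPV to `P_LP`, VUS to
#' `VUS`, LBV and BV to `B_LB`.  Vectorised; unknown labels are rejected.
#'
#' @param category Character vector of five-tier labels ([vc_tiers5()]).
#' @return Character vector of three-tier labels ([vc_tiers3()]).
#' @examples
#' consolidate(c("PV", "LPV", "VUS", "LBV", "BV"))
#' @export
consolidate <- function(category) {
  map <- c(PV = "P_LP", LPV = "P_LP", VUS = "VUS", LBV = "B_LB", BV = "B_LB")
  out <- map[as.character(category)]
  if (anyNA(out)) {
    bad <- unique(as.character(category)[is.na(out)])
    stop("unknown classification label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

new_classification <- function(category, total_points, evid, overrides,
                               engine, variant_id = NA_character_) {
  structure(
    list(variant_id = variant_id, category = category,
         total_points = as.integer(total_points), evidence = evid,
         overrides_applied = overrides, engine = engine),
    class = "vc_classification"
  )
}

#' @export
print.vc_classification <- function(x, ...) {
  cat(sprintf("<%s classification> %s (%+d points)\n",
              x$engine, x$category, x$total_points))
  if (nrow(x$evidence)) {
    lab <- sprintf("  %s %s (%+d)", x$evidence$code, x$evidence$strength,
                   x$evidence$points)
    flag <- ifelse(is.na(x$evidence$note), "", paste0(" [", x$evidence$note, "]"))
    cat(paste0(lab, flag, collapse = "\n"), "\n")
  } else {
    cat("  (no evidence triggered)\n")
  }
  if (length(x$overrides_applied))
    cat("  overrides:", paste(x$overrides_applied, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.vc_classification <- function(object, ...) {
  data.frame(
    variant_id = object$variant_id, engine = object$engine,
    category = object$category, tier = consolidate(object$category),
    total_points = object$total_points,
    n_evidence = nrow(object$evidence),
    codes = paste(sprintf("%s(%+d)", object$evidence$code,
                          object$evidence$points), collapse = ","),
    overrides = paste(object$overrides_applied, collapse = ","),
    stringsAsFactors = FALSE
  )
}
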