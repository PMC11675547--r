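# Generic automated (VarSome-style) points engine.  Shares the population
# test and the combination machinery, but draws computational evidence from
# MetaRNN calibration bins, applies its own category cut-points, and carries
# explicit toggles for the automated behaviours this engine emulates.

#' Computational evidence (PP3 / BP4) from MetaRNN calibration bins
#'
#' Maps a MetaRNN score through the configured monotone calibration bins to
#' PP3 (supporting to strong) for high scores or BP4 (supporting to strong)
#' for low scores; scores in the neutral band, or absent, yield no
#' evidence.  With `graded_bp4 = FALSE` the strength is capped at
#' supporting in both directions.
#'
#' @param bundle [annotation_bundle()] with a `metarnn` score.
#' @param cfg [auto_config()].
#' @return Evidence data frame with zero or one row.
#' @examples
#' assess_computational_auto(annotation_bundle(metarnn = 0.97))
#' @export
assess_computational_auto <- function(bundle, cfg = auto_config()) {
  m <- bundle$metarnn
  if (is.na(m)) return(empty_evidence())
  if (m < 0 || m > 1)
    stop("MetaRNN score must lie in [0, 1], got ", m, call. = FALSE)
  s <- lr_to_strength(m, cfg$metarnn_bins$pathogenic, "pathogenic")
  if (!is.na(s)) {
    if (!cfg$graded_bp4) s <- "supporting"
    return(evidence("PP3", s))
  }
  s <- lr_to_strength(m, cfg$metarnn_bins$benign, "benign")
  if (!is.na(s)) {
    if (!cfg$graded_bp4) s <- "supporting"
    return(evidence("BP4", s))
  }
  empty_evidence()
}

# extended BP1: any out-of-domain missense variant, no splice guard
assess_location_auto <- function(variant, cfg) {
  if (!cfg$apply_bp1_extended) return(empty_evidence())
  if (is.na(in_domain(variant$protein_position, cfg$domains)))
    return(evidence("BP1", "supporting", note = "extended"))
  empty_evidence()
}

# BP3 on missense variants flagged as lying in a repetitive region
assess_bp3_auto <- function(bundle, cfg) {
  if (cfg$apply_bp3_missense && isTRUE(bundle$repeat_region))
    return(evidence("BP3", "supporting"))
  empty_evidence()
}

#' Combine evidence under the generic engine's thresholds
#'
#' Same duplicate check, canonical code ordering and BA1 stand-alone
#' handling as [combine_canvig()], but without the gene-specific PM2
#' exclusion and VUS override, and with the generic category table
#' (PV >= 10, LPV 6..9, VUS 0..5, LBV -6..-1, BV <= -7).  The two engines'
#' totals agree on identical evidence; the category maps differ only at a
#' total of -6.
#'
#' @param evid Evidence data frame.
#' @param cfg [auto_config()].
#' @param variant_id Identifier attached to the result.
#' @return A `vc_classification` object.
#' @export
combine_auto <- function(evid, cfg = auto_config(),
                         variant_id = NA_character_) {
  combine_points(evid, cfg$thresholds, canvig_rules = FALSE,
                 engine = "auto", variant_id = variant_id)
}

#' Classify one missense variant with the generic automated engine
#'
#' Assembles evidence from the shared population test, same-residue
#' comparison (PM5 up to strong when `allow_pm5_strong`), MetaRNN
#' computational bins, the extended BP1 rule, BP3 for repeat-region
#' missense variants, and — only when `functional_visible` — the functional
#' assay result; then combines points through the generic thresholds with
#' no gene-specific overrides.
#'
#' @param variant [variant_record()] with `consequence = "missense"`.
#' @param bundle [annotation_bundle()].
#' @param cfg [auto_config()].
#' @return A `vc_classification` object.
#' @examples
#' v <- variant_record("v1", protein_position = 1200)
#' b <- annotation_bundle(allele_count = 0, allele_number = 100000,
#'                        metarnn = 0.1)
#' classify_variant_auto(v, b)
#' @export
classify_variant_auto <- function(variant, bundle, cfg = auto_config()) {
  stopifnot(inherits(variant, "vc_variant"), inherits(bundle, "vc_bundle"))
  if (variant$consequence != "missense")
    stop("engine accepts missense variants only; got '", variant$consequence,
         "' for ", variant$variant_id, call. = FALSE)
  pop_cfg <- canvig_config(freq = cfg$freq)  # shared population machinery
  evid <- evidence_table(
    assess_population(bundle, pop_cfg),
    if (cfg$functional_visible)
      assess_functional(bundle, cfg, variant$variant_id),
    pm5_assess(bundle, allow_strong = cfg$allow_pm5_strong),
    assess_computational_auto(bundle, cfg),
    assess_location_auto(variant, cfg),
    assess_bp3_auto(bundle, cfg)
  )
  combine_auto(evid, cfg, variant$variant_id)
}
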