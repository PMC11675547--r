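# Gene-specific (CanVIG-style) evidence assignment for BRCA1 missense
# variants.  Each assess_* operation inspects one evidence axis and returns
# zero or more evidence rows; classify_variant_canvig() runs them all and
# combines the points.

#' Population-frequency evidence (BA1 / BS1 / PM2)
#'
#' Applies the maximum-tolerated allele-count test at the BA1 and BS1
#' frequency thresholds.  Emits at most one of: BA1 (stand-alone) when the
#' observed count strictly exceeds the BA1 tolerance, BS1 (strong) when it
#' exceeds the BS1 tolerance, otherwise PM2 — at the configured strength for
#' complete absence from controls, at supporting for extremely low observed
#' frequency.  Absent count data always takes the PM2 path (benign
#' frequency evidence requires observed data).
#'
#' @param bundle [annotation_bundle()].
#' @param cfg [canvig_config()].
#' @return Evidence data frame with zero or one row.
#' @export
assess_population <- function(bundle, cfg = canvig_config()) {
  ac <- bundle$allele_count
  an <- bundle$allele_number
  if (is.na(ac) && !is.na(bundle$af) && !is.na(an))
    ac <- as.integer(round(bundle$af * an))
  conf <- cfg$freq$confidence
  if (!is.na(ac) && !is.na(an)) {
    if (isTRUE(exceeds_frequency_threshold(ac, an, cfg$freq$ba1_af, conf)))
      return(evidence("BA1", "standalone"))
    if (isTRUE(exceeds_frequency_threshold(ac, an, cfg$freq$bs1_af, conf)))
      return(evidence("BS1", "strong"))
    if (ac == 0L)
      return(evidence("PM2", cfg$pm2_absent_strength, note = "absent"))
    return(evidence("PM2", "supporting", note = "extremely_low"))
  }
  # no usable count data: treat as absent from controls
  evidence("PM2", cfg$pm2_absent_strength, note = "absent")
}

#' Functional assay evidence (PS3 / BS3)
#'
#' Abnormal assay results yield PS3 and normal results BS3, each at the
#' strength grade supplied with the assay.  A splice-affecting result yields
#' PS3 with the splice-effect annotation retained.  Intermediate or missing
#' results yield no evidence.
#'
#' @param bundle [annotation_bundle()].
#' @param cfg Engine config (unused; kept for a uniform signature).
#' @param variant_id Identifier used in error messages.
#' @return Evidence data frame with zero or one row.
#' @export
assess_functional <- function(bundle, cfg = canvig_config(),
                              variant_id = "<unknown>") {
  fr <- bundle$functional_result
  if (fr %in% c("none", "intermediate")) return(empty_evidence())
  if (is.na(bundle$assay_strength))
    stop("functional result '", fr, "' without an assay strength for variant ",
         variant_id, call. = FALSE)
  switch(fr,
    abnormal = evidence("PS3", bundle$assay_strength),
    splice_effect = evidence("PS3", bundle$assay_strength,
                             note = "splice_effect"),
    normal = evidence("BS3", bundle$assay_strength))
}

# shared PM5 logic; the auto engine may upgrade to strong for PV references
pm5_assess <- function(bundle, allow_strong = FALSE) {
  refs <- bundle$same_residue_refs
  if (is.null(refs) || nrow(refs) == 0L) return(empty_evidence())
  if (anyNA(refs$classification) ||
      !all(refs$classification %in% c("PV", "LPV")))
    stop("same-residue reference without a PV/LPV classification",
         call. = FALSE)
  strength_rank <- c(supporting = 1L, moderate = 2L, strong = 3L)
  best <- "supporting"
  for (i in seq_len(nrow(refs))) {
    ref <- refs[i, ]
    if (ref$classification == "LPV" && isTRUE(ref$limited_reports)) {
      s <- "supporting"
    } else if (!is.na(bundle$revel) && !is.na(ref$revel) &&
               bundle$revel >= ref$revel) {
      s <- if (allow_strong && ref$classification == "PV") "strong" else "moderate"
    } else {
      s <- "supporting"
    }
    if (strength_rank[s] > strength_rank[best]) best <- s
  }
  evidence("PM5", best)
}

#' Same-residue evidence (PM5)
#'
#' Applies PM5 when a different missense change at the same residue has been
#' classified PV or LPV: moderate when the query REVEL is at least as
#' deleterious as the reference, supporting when it is less deleterious or
#' the reference is an LPV resting on limited reports.  At most one PM5 is
#' emitted (the strongest applicable across references).
#'
#' @param variant [variant_record()] (identifies the residue; references are
#'   supplied pre-matched in the bundle).
#' @param bundle [annotation_bundle()] with `same_residue_refs`.
#' @param cfg [canvig_config()].
#' @return Evidence data frame with zero or one row.
#' @export
assess_same_residue <- function(variant, bundle, cfg = canvig_config()) {
  pm5_assess(bundle, allow_strong = FALSE)
}

# map a likelihood ratio onto graded strength via monotone bins
lr_to_strength <- function(lr, cuts, direction) {
  cuts <- sort(cuts)  # ascending cut values
  if (direction == "pathogenic") {
    hit <- names(cuts)[lr >= cuts]
    if (!length(hit)) return(NA_character_)
    hit[length(hit)]
  } else {
    hit <- names(cuts)[lr <= cuts]
    if (!length(hit)) return(NA_character_)
    hit[1L]
  }
}

#' Multifactorial likelihood evidence (PP5 / BP6)
#'
#' Maps a published multifactorial likelihood ratio through the configured
#' monotone bins: ratios above 1 toward PP5 (supporting to very strong),
#' ratios below 1 toward BP6 (supporting to strong).  Ratios inside the
#' neutral band, or absent, yield no evidence.
#'
#' @param bundle [annotation_bundle()].
#' @param cfg [canvig_config()].
#' @return Evidence data frame with zero or one row.
#' @export
assess_multifactorial <- function(bundle, cfg = canvig_config()) {
  lr <- bundle$multifactorial_lr
  if (is.na(lr)) return(empty_evidence())
  if (!is.finite(lr) || lr <= 0)
    stop("multifactorial likelihood ratio must be positive, got ", lr,
         call. = FALSE)
  if (lr > 1) {
    s <- lr_to_strength(lr, cfg$lr_bins$pathogenic, "pathogenic")
    if (is.na(s)) return(empty_evidence())
    return(evidence("PP5", s))
  }
  if (lr < 1) {
    s <- lr_to_strength(lr, cfg$lr_bins$benign, "benign")
    if (is.na(s)) return(empty_evidence())
    return(evidence("BP6", s))
  }
  empty_evidence()  # LR exactly 1: neutral
}

#' In-silico missense evidence (PP3 / BP4) from REVEL
#'
#' PP3 supporting when REVEL strictly exceeds the damaging cut (0.7), BP4
#' supporting when strictly below the benign cut (0.4); the interval between
#' the cuts, and absent scores, yield no evidence.
#'
#' @param bundle [annotation_bundle()].
#' @param cfg [canvig_config()].
#' @return Evidence data frame with zero or one row.
#' @export
assess_insilico <- function(bundle, cfg = canvig_config()) {
  r <- bundle$revel
  if (is.na(r)) return(empty_evidence())
  if (r > cfg$revel_pp3) return(evidence("PP3", "supporting"))
  if (r < cfg$revel_bp4) return(evidence("BP4", "supporting"))
  empty_evidence()
}

in_domain <- function(position, domains) {
  hit <- which(position >= domains$start_aa & position <= domains$end_aa)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Location evidence (PM1 / BP1)
#'
#' Variants inside a configured functional domain earn PM1 — moderate for
#' residues on the configured critical-residue list, otherwise at the
#' domain's default (supporting).  Variants outside all domains earn BP1
#' supporting provided no splice effect is predicted (score below the guard,
#' or score absent when the config allows it); a predicted splice effect
#' blocks BP1.
#'
#' @param variant [variant_record()].
#' @param bundle [annotation_bundle()].
#' @param cfg [canvig_config()].
#' @return Evidence data frame with zero or one row.
#' @export
assess_location <- function(variant, bundle, cfg = canvig_config()) {
  pos <- variant$protein_position
  d <- in_domain(pos, cfg$domains)
  if (!is.na(d)) {
    s <- if (pos %in% cfg$pm1_moderate_residues) "moderate"
         else cfg$domains$pm1_strength[d]
    return(evidence("PM1", s, note = cfg$domains$name[d]))
  }
  sp <- bundle$splice_score
  if (is.na(sp)) {
    if (cfg$bp1_when_splice_absent) return(evidence("BP1", "supporting"))
    return(empty_evidence())
  }
  if (sp < cfg$splice_bp1_max) return(evidence("BP1", "supporting"))
  empty_evidence()
}

#' Case-control enrichment evidence (PS4)
#'
#' PS4 applies at the configured strength when the case-control odds ratio
#' meets the inclusive threshold (OR >= 10 by default).
#'
#' @param bundle [annotation_bundle()].
#' @param cfg [canvig_config()].
#' @return Evidence data frame with zero or one row.
#' @export
assess_case_control <- function(bundle, cfg = canvig_config()) {
  or <- bundle$case_control_or
  if (is.na(or)) return(empty_evidence())
  if (!is.finite(or) || or <= 0)
    stop("case-control odds ratio must be positive, got ", or, call. = FALSE)
  if (or >= cfg$ps4_or_min) return(evidence("PS4", cfg$ps4_strength))
  empty_evidence()
}

# PS1: an input flag asserts an identical amino-acid change already
# classified pathogenic; applied at established (strong) strength.
assess_ps1 <- function(bundle) {
  if (isTRUE(bundle$same_aa_pathogenic)) evidence("PS1", "strong")
  else empty_evidence()
}

#' Combine evidence under the gene-specific rules
#'
#' Sums signed points and maps the total through the gene-specific category
#' thresholds, applying three rules in order:
#' \enumerate{
#'   \item BA1 present: the variant is BV by stand-alone override.
#'   \item PM2 exclusion: when PM2 is the only pathogenic-direction element
#'     and the remaining sum lies in benign territory, PM2 is dropped from
#'     the total ("disregarding PM2 when benignity is strongly supported").
#'   \item VUS override: when the mapped category is LBV or BV but two or
#'     more pathogenic-direction elements are present, the variant is
#'     returned as VUS.
#' }
#' Evidence is canonically sorted by code first, so the result is
#' order-independent; duplicate codes are rejected.
#'
#' @param evid Evidence data frame (rows from the `assess_*` operations).
#' @param cfg [canvig_config()].
#' @param variant_id Identifier attached to the result.
#' @return A `vc_classification` object.
#' @examples
#' combine_canvig(evidence_table(evidence("PS3", "strong"),
#'                               evidence("PM2", "supporting"),
#'                               evidence("PP3", "supporting")))
#' @export
combine_canvig <- function(evid, cfg = canvig_config(),
                           variant_id = NA_character_) {
  combine_points(evid, cfg$thresholds, canvig_rules = TRUE,
                 engine = "canvig", variant_id = variant_id)
}

# shared combiner; canvig_rules gates the PM2-exclusion and VUS-override
combine_points <- function(evid, thresholds, canvig_rules, engine,
                           variant_id = NA_character_) {
  stopifnot(is.data.frame(evid))
  if (anyDuplicated(evid$code))
    stop("duplicate evidence codes in one combination: ",
         paste(evid$code[duplicated(evid$code)], collapse = ", "),
         call. = FALSE)
  evid <- evid[order(evid$code), , drop = FALSE]
  rownames(evid) <- NULL
  overrides <- character()
  total <- sum(evid$points)

  if ("BA1" %in% evid$code) {
    return(new_classification("BV", total, evid, "ba1_standalone",
                              engine, variant_id))
  }

  if (canvig_rules && "PM2" %in% evid$code) {
    pathogenic <- evid$code[evid$direction == "pathogenic"]
    if (identical(pathogenic, "PM2")) {
      remaining <- total - evid$points[evid$code == "PM2"]
      if (remaining <= -1L) {        # benign territory: LBV or BV
        total <- remaining
        overrides <- c(overrides, "pm2_excluded")
      }
    }
  }

  category <- map_category(total, thresholds)

  if (canvig_rules && category %in% c("LBV", "BV") &&
      sum(evid$direction == "pathogenic") >= 2L) {
    category <- "VUS"
    overrides <- c(overrides, "vus_override")
  }

  new_classification(category, total, evid, overrides, engine, variant_id)
}

#' Classify one missense variant with the gene-specific engine
#'
#' Runs every evidence assessment (population, functional, same-residue,
#' multifactorial, in-silico, location, case-control, PS1 flag) and combines
#' the triggered evidence with [combine_canvig()].  Deterministic for fixed
#' inputs and config; non-missense variants are rejected.
#'
#' @param variant [variant_record()] with `consequence = "missense"`.
#' @param bundle [annotation_bundle()].
#' @param cfg [canvig_config()].
#' @return A `vc_classification` object.
#' @examples
#' v <- variant_record("v1", protein_position = 1200)
#' b <- annotation_bundle(allele_count = 0, allele_number = 100000,
#'                        revel = 0.85, splice_score = 0.5)
#' classify_variant_canvig(v, b)
#' @export
classify_variant_canvig <- function(variant, bundle, cfg = canvig_config()) {
  stopifnot(inherits(variant, "vc_variant"), inherits(bundle, "vc_bundle"))
  if (variant$consequence != "missense")
    stop("engine accepts missense variants only; got '", variant$consequence,
         "' for ", variant$variant_id, call. = FALSE)
  evid <- evidence_table(
    assess_population(bundle, cfg),
    assess_functional(bundle, cfg, variant$variant_id),
    assess_same_residue(variant, bundle, cfg),
    assess_multifactorial(bundle, cfg),
    assess_insilico(bundle, cfg),
    assess_location(variant, bundle, cfg),
    assess_case_control(bundle, cfg),
    assess_ps1(bundle)
  )
  combine_canvig(evid, cfg, variant$variant_id)
}
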