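# Engine configurations.  All tunables live here so a run can serialize its
# exact settings alongside its outputs.

#' Default BRCA1 functional-domain table
#'
#' Closed 1-based amino-acid intervals for the RING, COILED-COIL and BRCT
#' domains.  Methods-style boundaries are the default (RING 1-101, BRCT
#' 1650-1863); the alternative printed boundaries (RING 2-101, BRCT
#' 1650-1857) can be supplied by passing a modified table to the config.
#'
#' @return Data frame with columns `name`, `start_aa`, `end_aa`,
#'   `pm1_strength`.
#' @export
brca1_domains <- function() {
  data.frame(
    name = c("RING", "COILED-COIL", "BRCT"),
    start_aa = c(1L, 1391L, 1650L),
    end_aa = c(101L, 1424L, 1863L),
    pm1_strength = c("supporting", "supporting", "supporting"),
    stringsAsFactors = FALSE
  )
}

# Tavtigian-style likelihood-ratio bins: the odds of pathogenicity that
# correspond to supporting/moderate/strong/very-strong evidence, with
# reciprocals toward benignity (benign capped at strong).
default_lr_bins <- function() {
  list(
    pathogenic = c(supporting = 2.08, moderate = 4.33, strong = 18.7,
                   very_strong = 350),
    benign = c(supporting = 1 / 2.08, moderate = 1 / 4.33, strong = 1 / 18.7)
  )
}

# Graded MetaRNN calibration bins for the auto engine (config data, not a
# published table): scores at or above a pathogenic cut map to PP3 at that
# strength, scores at or below a benign cut map to BP4.
default_metarnn_bins <- function() {
  list(
    pathogenic = c(supporting = 0.70, moderate = 0.85, strong = 0.94),
    benign = c(supporting = 0.40, moderate = 0.20, strong = 0.05)
  )
}

validate_domains <- function(domains) {
  stopifnot(is.data.frame(domains),
            all(c("name", "start_aa", "end_aa", "pm1_strength") %in%
                  names(domains)))
  if (any(domains$start_aa < 1L) || any(domains$end_aa < domains$start_aa))
    stop("domain intervals must be closed, 1-based and non-empty",
         call. = FALSE)
  if (nrow(domains) > 1L) {
    o <- order(domains$start_aa)
    s <- domains[o, ]
    if (any(s$start_aa[-1L] <= s$end_aa[-nrow(s)]))
      stop("domain intervals overlap", call. = FALSE)
  }
  invisible(domains)
}

validate_bins <- function(bins, benign_max = "strong") {
  stopifnot(is.list(bins), all(c("pathogenic", "benign") %in% names(bins)))
  if (is.unsorted(unname(bins$pathogenic)) &&
      is.unsorted(rev(unname(bins$pathogenic))))
    stop("pathogenic bins must be monotone", call. = FALSE)
  invisible(bins)
}

#' Configuration for the gene-specific (CanVIG-style) engine
#'
#' Holds every tunable of the gene-specific BRCA1 missense engine: frequency
#' thresholds, REVEL cut-offs for PP3/BP4, the splice-score guard for BP1,
#' the case-control odds-ratio threshold for PS4, the functional-domain
#' table for PM1/BP1, likelihood-ratio bins for PP5/BP6, and the category
#' threshold table PV >= 10, LPV 6..9, VUS 0..5, LBV -5..-1, BV <= -6.
#'
#' @param freq [frequency_thresholds()].
#' @param revel_pp3 REVEL above which PP3 applies (strict; default 0.7).
#' @param revel_bp4 REVEL below which BP4 applies (strict; default 0.4).
#' @param splice_bp1_max Splice score at or above which BP1 is blocked
#'   (default 0.2).
#' @param ps4_or_min Odds ratio at or above which PS4 applies (default 10).
#' @param ps4_strength Strength assigned to PS4 (default `"strong"`; the
#'   guidance permits very strong to supporting).
#' @param domains Domain table as in [brca1_domains()].
#' @param pm1_moderate_residues Integer vector of residues inside domains
#'   that earn PM1 at moderate rather than the domain default (default
#'   empty).
#' @param lr_bins Likelihood-ratio bins (list with `pathogenic` and `benign`
#'   named cut vectors) for PP5/BP6.
#' @param pm2_absent_strength Strength of PM2 when the variant is absent
#'   from controls (default `"supporting"`, switchable to `"moderate"`).
#' @param bp1_when_splice_absent Apply BP1 outside domains when no splice
#'   score is available (default `TRUE`).
#' @return A list of class `vc_canvig_config`.
#' @examples
#' cfg <- canvig_config()
#' cfg$thresholds
#' @export
canvig_config <- function(freq = frequency_thresholds(),
                          revel_pp3 = 0.7, revel_bp4 = 0.4,
                          splice_bp1_max = 0.2,
                          ps4_or_min = 10, ps4_strength = "strong",
                          domains = brca1_domains(),
                          pm1_moderate_residues = integer(),
                          lr_bins = default_lr_bins(),
                          pm2_absent_strength = "supporting",
                          bp1_when_splice_absent = TRUE) {
  stopifnot(inherits(freq, "vc_freq_thresholds"))
  validate_domains(domains)
  validate_bins(lr_bins)
  ps4_strength <- match.arg(ps4_strength,
                            c("very_strong", "strong", "moderate", "supporting"))
  pm2_absent_strength <- match.arg(pm2_absent_strength,
                                   c("supporting", "moderate"))
  if (!(revel_pp3 > revel_bp4))
    stop("revel_pp3 must exceed revel_bp4", call. = FALSE)
  structure(
    list(freq = freq, revel_pp3 = revel_pp3, revel_bp4 = revel_bp4,
         splice_bp1_max = splice_bp1_max, ps4_or_min = ps4_or_min,
         ps4_strength = ps4_strength, domains = domains,
         pm1_moderate_residues = as.integer(pm1_moderate_residues),
         lr_bins = lr_bins, pm2_absent_strength = pm2_absent_strength,
         bp1_when_splice_absent = isTRUE(bp1_when_splice_absent),
         thresholds = c(pv_min = 10L, lpv_min = 6L, vus_min = 0L,
                        lbv_min = -5L)),
    class = "vc_canvig_config"
  )
}

#' Configuration for the generic automated (VarSome-style) engine
#'
#' The generic points engine shares the evidence-combination machinery but
#' uses its own category cut-points (LBV spans -6..-1 and BV requires
#' <= -7), MetaRNN-driven computational evidence, and explicit toggles
#' emulating behaviours observed of the automated tool: BP3 on missense
#' variants in repeat regions, BP1 extended to all out-of-domain missense
#' variants, PM5 allowed up to strong, and graded (supporting-to-strong)
#' BP4/PP3.
#'
#' @param freq [frequency_thresholds()] (generic population test; same
#'   defaults as the gene-specific engine).
#' @param metarnn_bins MetaRNN calibration bins (list with `pathogenic` and
#'   `benign` named cut vectors).
#' @param domains Domain table used by the extended BP1 rule.
#' @param apply_bp3_missense Emit BP3 for repeat-region missense variants
#'   (default `TRUE`).
#' @param apply_bp1_extended Emit BP1 for any out-of-domain missense variant
#'   regardless of splice predictions (default `TRUE`).
#' @param allow_pm5_strong Allow PM5 up to strong when the query is at least
#'   as deleterious as a PV reference (default `TRUE`).
#' @param graded_bp4 Use the graded strength from the calibration bins; when
#'   `FALSE`, computational evidence is capped at supporting (default
#'   `TRUE`).
#' @param functional_visible Whether functional assay results reach this
#'   engine (default `FALSE`: the automated tool typically lacks applied
#'   functional evidence).
#' @return A list of class `vc_auto_config`.
#' @examples
#' auto_config()$thresholds
#' @export
auto_config <- function(freq = frequency_thresholds(),
                        metarnn_bins = default_metarnn_bins(),
                        domains = brca1_domains(),
                        apply_bp3_missense = TRUE,
                        apply_bp1_extended = TRUE,
                        allow_pm5_strong = TRUE,
                        graded_bp4 = TRUE,
                        functional_visible = FALSE) {
  stopifnot(inherits(freq, "vc_freq_thresholds"))
  validate_domains(domains)
  validate_bins(metarnn_bins)
  structure(
    list(freq = freq, metarnn_bins = metarnn_bins, domains = domains,
         apply_bp3_missense = isTRUE(apply_bp3_missense),
         apply_bp1_extended = isTRUE(apply_bp1_extended),
         allow_pm5_strong = isTRUE(allow_pm5_strong),
         graded_bp4 = isTRUE(graded_bp4),
         functional_visible = isTRUE(functional_visible),
         thresholds = c(pv_min = 10L, lpv_min = 6L, vus_min = 0L,
                        lbv_min = -6L)),
    class = "vc_auto_config"
  )
}

#' Map a point total to a five-tier category under a threshold table
#'
#' @param total Signed integer point total (vectorised).
#' @param thresholds Named vector with `pv_min`, `lpv_min`, `vus_min`,
#'   `lbv_min`, as stored in an engine config.
#' @return Character vector of five-tier categories.
#' @examples
#' map_category(-6, canvig_config()$thresholds)  # BV
#' map_category(-6, auto_config()$thresholds)    # LBV
#' @export
map_category <- function(total, thresholds) {
  ifelse(total >= thresholds[["pv_min"]], "PV",
  ifelse(total >= thresholds[["lpv_min"]], "LPV",
  ifelse(total >= thresholds[["vus_min"]], "VUS",
  ifelse(total >= thresholds[["lbv_min"]], "LBV", "BV"))))
}
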