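# Bundled reference data: the printed summary tables from a published
# reinterpretation study of 450 conflicting ClinVar BRCA1 missense variants,
# used as worked-example inputs for the arithmetic and consolidation
# operations (the study's per-variant appendix is not redistributed).

#' Reference consensus-update table (17 variants)
#'
#' The 17 of 450 conflicting BRCA1 missense variants that reached a
#' single-tier ClinVar consensus at the later snapshot, with the two
#' engines' earlier interpretations and the consolidated consensus tier.
#'
#' @return Data frame with columns `no`, `hgvs_c`, `hgvs_p`,
#'   `n_submissions`, `pct_plp_2022`, `pct_vus_2022`, `pct_blb_2022`,
#'   `varsome`, `canvig`, `consensus_2024`.
#' @examples
#' head(reference_consensus_table())
#' @export
reference_consensus_table <- function() {
  path <- system.file("extdata", "table3_consensus.tsv",
                      package = "varconcord", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference per-tier classification counts for the 450-variant cohort
#'
#' @return A list with named integer vectors `varsome` and `canvig`
#'   (counts over `P_LP`, `VUS`, `B_LB`; each sums to 450).
#' @export
reference_distribution_counts <- function() {
  list(
    varsome = c(P_LP = 51L, VUS = 111L, B_LB = 288L),
    canvig = c(P_LP = 50L, VUS = 232L, B_LB = 168L)
  )
}

#' Reference submitter-stratified agreement counts
#'
#' Stratum sizes and engine matches for the focal tiers: variants where
#' more than 50% / at most 50% (but at least one) / at least one countable
#' ClinVar submitter asserted the tier, against each engine's agreement
#' count in that tier.
#'
#' @return Data frame with columns `tier`, `stratum`, `engine`, `n`,
#'   `matches`.
#' @export
reference_agreement_strata <- function() {
  data.frame(
    tier = c(rep("P_LP", 6), rep("B_LB", 6)),
    stratum = rep(c("majority", "minority", "any"), 4),
    engine = rep(c("varsome", "varsome", "varsome",
                   "canvig", "canvig", "canvig"), 2),
    n = c(21L, 34L, 55L, 21L, 34L, 55L, 66L, 329L, 395L, 66L, 329L, 395L),
    matches = c(19L, 18L, 37L, 20L, 30L, 50L,
                54L, 233L, 287L, 48L, 120L, 168L),
    stringsAsFactors = FALSE
  )
}

#' Reference overall concordance count
#'
#' @return Named integer vector: `concordant = 265`, `n = 450`.
#' @export
reference_concordance <- function() {
  c(concordant = 265L, n = 450L)
}
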