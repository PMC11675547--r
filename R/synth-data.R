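# Synthetic cohort generation.  Emulates the statistical structure of a
# conflicting-missense-variant cohort: positions concentrated in the RING
# and BRCT domains, 2-15 submitters per variant with elevated mass at 2, 3
# and 5, sparse functional/multifactorial evidence, correlated REVEL and
# MetaRNN scores, and a zero-inflated rare allele-frequency model.  A later
# snapshot resolves a small fraction of variants to consensus.

#' Specification for a synthetic conflicting-variant cohort
#'
#' Defaults mirror the cohort structure the package's analyses assume:
#' 450 conflicting missense variants, positions drawn mostly from the RING
#' and BRCT domains, submitter counts on 2..15 with modes at 2, 3 and 5
#' (probabilities proportional to the observed 91/85/73-variant peaks), and
#' about 4% of variants (17/450) resolving to consensus in the second
#' snapshot.
#'
#' @param n_variants Number of variants (default 450).
#' @param seed Integer seed; every draw in [generate_cohort()] flows from it.
#' @param domain_weights Named probabilities for sampling positions from
#'   RING / BRCT / COILED-COIL / outside (must sum to 1).
#' @param submitter_probs Named probability table over submitter counts
#'   2..15 (must sum to 1).
#' @param availability Per-field presence probabilities for the sparse
#'   evidence inputs.
#' @param score_correlation Latent correlation between REVEL and MetaRNN
#'   (default 0.7).
#' @param pathogenic_component Mixture weight of the pathogenic-leaning
#'   score component (default 0.35).
#' @param zero_af_prob Probability that a variant is absent from controls
#'   (default 0.6); otherwise AF is log-uniform on `[1e-6, 1e-3]`.
#' @param resolve_fraction Fraction of variants whose second snapshot
#'   reaches consensus (default `17 / 450`).
#' @param tier_probs Five-tier probabilities for submitter assertions.
#' @return A list of class `vc_cohort_spec`.
#' @export
cohort_spec <- function(n_variants = 450L, seed = 1L,
                        domain_weights = c(RING = 0.40, BRCT = 0.40,
                                           `COILED-COIL` = 0.05,
                                           outside = 0.15),
                        submitter_probs = default_submitter_probs(),
                        availability = c(revel = 0.95, metarnn = 0.95,
                                         splice = 0.30, functional = 0.15,
                                         lr = 0.08, or = 0.05,
                                         same_residue = 0.10),
                        score_correlation = 0.7,
                        pathogenic_component = 0.35,
                        zero_af_prob = 0.6,
                        resolve_fraction = 17 / 450,
                        tier_probs = c(PV = 0.10, LPV = 0.10, VUS = 0.40,
                                       LBV = 0.25, BV = 0.15)) {
  n_variants <- as.integer(n_variants)
  if (is.na(n_variants) || n_variants < 1L)
    stop("n_variants must be >= 1", call. = FALSE)
  for (p in list(domain_weights, submitter_probs, tier_probs))
    if (abs(sum(p) - 1) > 1e-8)
      stop("probability table does not sum to 1", call. = FALSE)
  if (length(unique(consolidate(names(tier_probs)[tier_probs > 0]))) < 2L)
    stop("tier_probs gives zero probability of conflict", call. = FALSE)
  if (resolve_fraction < 0 || resolve_fraction > 1)
    stop("resolve_fraction must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_variants = n_variants, seed = as.integer(seed),
         domain_weights = domain_weights, submitter_probs = submitter_probs,
         availability = availability, score_correlation = score_correlation,
         pathogenic_component = pathogenic_component,
         zero_af_prob = zero_af_prob, resolve_fraction = resolve_fraction,
         tier_probs = tier_probs),
    class = "vc_cohort_spec"
  )
}

#' Default submitter-count distribution (2..15, modes at 2, 3, 5)
#'
#' @return Named probability vector over counts 2..15.
#' @export
default_submitter_probs <- function() {
  p <- c(`2` = 0.202, `3` = 0.189, `4` = 0.110, `5` = 0.162, `6` = 0.080,
         `7` = 0.060, `8` = 0.050, `9` = 0.040, `10` = 0.030, `11` = 0.025,
         `12` = 0.020, `13` = 0.015, `14` = 0.010, `15` = 0.007)
  p / sum(p)
}

aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

sample_positions <- function(n, weights, domains) {
  regions <- list(
    RING = domains$start_aa[1]:domains$end_aa[1],
    `COILED-COIL` = domains$start_aa[2]:domains$end_aa[2],
    BRCT = domains$start_aa[3]:domains$end_aa[3]
  )
  all_dom <- unlist(regions, use.names = FALSE)
  regions$outside <- setdiff(seq_len(max(domains$end_aa)), all_dom)
  which_region <- sample(names(weights), n, replace = TRUE, prob = weights)
  vapply(which_region, function(r)
    regions[[r]][sample.int(length(regions[[r]]), 1L)], integer(1),
    USE.NAMES = FALSE)
}

# assertion tiers for one conflicting variant: rejection-sample until the
# assertion-criteria subset spans >= 2 consolidated tiers
draw_conflicting_tiers <- function(n_sub, tier_probs) {
  for (i in 1:1000) {
    cls <- sample(names(tier_probs), n_sub, replace = TRUE,
                  prob = tier_probs)
    ac <- c(TRUE, TRUE, stats::runif(max(n_sub - 2L, 0L)) < 0.9)[seq_len(n_sub)]
    if (length(unique(consolidate(cls[ac]))) >= 2L)
      return(list(classification = cls, assertion_criteria = ac))
  }
  stop("could not draw a conflicting submission set; check tier_probs",
       call. = FALSE)
}

#' Generate a synthetic conflicting-variant cohort
#'
#' Draws variants, annotation bundles and per-variant submission sets at
#' two snapshot dates.  Every first-snapshot set is conflicting by
#' construction (tier assignments are rejection-sampled until the
#' assertion-criteria submissions span at least two consolidated tiers);
#' the second snapshot resolves a `resolve_fraction` of variants to a
#' single-tier consensus.  Fully reproducible for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `vc_cohort`: `variants` (list of
#'   [variant_record()]), `bundles` (list of [annotation_bundle()]),
#'   `sets_t1` and `sets_t2` (lists of `vc_submission_set`), and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_variants = 5, seed = 7))
#' cohort$variants[[1]]
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "vc_cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_variants
  domains <- brca1_domains()
  pos <- sample_positions(n, spec$domain_weights, domains)
  ref_aa <- sample(aa3, n, replace = TRUE)
  alt_aa <- sample(aa3, n, replace = TRUE)
  swap <- alt_aa == ref_aa
  alt_aa[swap] <- aa3[(match(ref_aa[swap], aa3) %% length(aa3)) + 1L]

  variants <- lapply(seq_len(n), function(i)
    variant_record(sprintf("SYN%04d", i), gene = "BRCA1",
                   hgvs_c = sprintf("c.%dN>N", 3L * pos[i] - 1L),
                   hgvs_p = sprintf("p.%s%d%s", ref_aa[i], pos[i], alt_aa[i]),
                   protein_position = pos[i]))

  # correlated REVEL / MetaRNN from a two-component latent Gaussian model
  comp <- stats::runif(n) < spec$pathogenic_component
  mu <- ifelse(comp, 1.0, -1.0)
  z1 <- stats::rnorm(n)
  z2 <- spec$score_correlation * z1 +
    sqrt(1 - spec$score_correlation^2) * stats::rnorm(n)
  revel <- stats::pnorm(mu + z1)
  metarnn <- stats::pnorm(mu + z2)

  av <- spec$availability
  bundles <- vector("list", n)
  for (i in seq_len(n)) {
    an <- as.integer(round(stats::runif(1, 5e4, 1.2e5)))
    if (stats::runif(1) < spec$zero_af_prob) {
      ac <- 0L; af <- 0
    } else {
      af <- 10^stats::runif(1, -6, -3)
      ac <- as.integer(round(af * an))
    }
    fun_res <- "none"; fun_str <- NA_character_
    if (stats::runif(1) < av[["functional"]]) {
      fun_res <- sample(c("abnormal", "normal", "splice_effect",
                          "intermediate"), 1L,
                        prob = c(0.40, 0.45, 0.10, 0.05))
      if (fun_res != "intermediate")
        fun_str <- sample(c("strong", "moderate", "supporting"), 1L,
                          prob = c(0.5, 0.3, 0.2))
    }
    refs <- NULL
    if (stats::runif(1) < av[["same_residue"]]) {
      refs <- same_residue_ref(
        hgvs_p = sprintf("p.%s%dXaa", ref_aa[i], pos[i]),
        classification = sample(c("PV", "LPV"), 1L, prob = c(0.6, 0.4)),
        revel = stats::runif(1, 0.6, 0.99),
        limited_reports = stats::runif(1) < 0.3)
    }
    bundles[[i]] <- annotation_bundle(
      af = af, allele_count = ac, allele_number = an,
      revel = if (stats::runif(1) < av[["revel"]]) revel[i] else NA_real_,
      metarnn = if (stats::runif(1) < av[["metarnn"]]) metarnn[i] else NA_real_,
      splice_score = if (stats::runif(1) < av[["splice"]])
        stats::rbeta(1, 0.5, 4) else NA_real_,
      functional_result = fun_res, assay_strength = fun_str,
      multifactorial_lr = if (stats::runif(1) < av[["lr"]])
        exp(stats::rnorm(1, 0, 2.5)) else NA_real_,
      case_control_or = if (stats::runif(1) < av[["or"]])
        stats::rlnorm(1, 1.5, 1) else NA_real_,
      same_residue_refs = refs,
      repeat_region = stats::runif(1) < 0.12
    )
  }

  counts <- as.integer(sample(names(spec$submitter_probs), n, replace = TRUE,
                              prob = spec$submitter_probs))
  sets_t1 <- vector("list", n)
  for (i in seq_len(n)) {
    drawn <- draw_conflicting_tiers(counts[i], spec$tier_probs)
    subs <- data.frame(
      submitter_id = sprintf("SUB%03d", sample.int(500, counts[i])),
      classification = drawn$classification,
      assertion_criteria = drawn$assertion_criteria,
      snapshot_date = "2022-12-20",
      stringsAsFactors = FALSE
    )
    sets_t1[[i]] <- structure(list(variant = variants[[i]],
                                   submissions = subs),
                              class = "vc_submission_set")
  }

  n_resolve <- as.integer(round(spec$resolve_fraction * n))
  resolve_idx <- if (n_resolve) sample.int(n, n_resolve) else integer()
  sets_t2 <- vector("list", n)
  for (i in seq_len(n)) {
    subs <- sets_t1[[i]]$submissions
    subs$snapshot_date <- "2024-05-01"
    if (i %in% resolve_idx) {
      tier <- sample(vc_tiers3(), 1L, prob = c(0.5, 0.1, 0.4))
      five <- switch(tier,
        P_LP = sample(c("PV", "LPV"), nrow(subs), replace = TRUE),
        VUS = rep("VUS", nrow(subs)),
        B_LB = sample(c("BV", "LBV"), nrow(subs), replace = TRUE))
      subs$classification <- five
    }
    sets_t2[[i]] <- structure(list(variant = variants[[i]],
                                   submissions = subs),
                              class = "vc_submission_set")
  }

  structure(list(variants = variants, bundles = bundles,
                 sets_t1 = sets_t1, sets_t2 = sets_t2, spec = spec),
            class = "vc_cohort")
}

#' @export
print.vc_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort> %d missense variants (seed %d)\n",
              length(x$variants), x$spec$seed))
  cat(sprintf("  resolved to consensus at second snapshot: %d\n",
              sum(!is.na(vapply(x$sets_t2, detect_consensus, character(1))))))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Curated boundary fixtures for the classification engines
#'
#' Deterministic (variant, bundle, expected-outcome) triples exercising
#' every decision boundary of the engines: REVEL at 0.39/0.40/0.70/0.71,
#' splice guard at 0.19/0.20, odds ratio at 9.9/10, allele counts one
#' either side of the BS1 and BA1 tolerances, and point totals at every
#' category cut (-7, -6, -5, -1, 0, 5, 6, 9, 10) — including the total of
#' -6 where the two engines' threshold tables diverge (BV under the
#' gene-specific table, LBV under the generic one).  Expected categories,
#' totals and triggered codes were derived by hand from the rule
#' definitions and are frozen here.
#'
#' @return A list of fixtures; each has `name`, `variant`, `bundle`,
#'   `expect_canvig` (list: `category`, `total`, `codes`, `overrides`) and
#'   optionally `expect_auto`.
#' @export
generate_boundary_fixtures <- function() {
  an <- 100000L
  bs1_tol <- as.integer(stats::qpois(0.95, 0.0001 * an))  # base-R input prep
  ba1_tol <- as.integer(stats::qpois(0.95, 0.001 * an))
  v_out <- function(id) variant_record(id, protein_position = 1200L)
  v_ring <- function(id) variant_record(id, protein_position = 50L)
  fx <- list()
  add <- function(name, variant, bundle, canvig, auto = NULL) {
    fx[[length(fx) + 1L]] <<- list(name = name, variant = variant,
                                   bundle = bundle, expect_canvig = canvig,
                                   expect_auto = auto)
  }
  exp_ <- function(category, total, codes, overrides = character())
    list(category = category, total = total, codes = sort(codes),
         overrides = overrides)

  # REVEL boundaries (AC=0 -> PM2; pos 1200 splice 0.5 blocks BP1/PM1)
  add("revel_0.71_pp3", v_out("fx_r71"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.71,
                        splice_score = 0.5),
      exp_("VUS", 2L, c("PM2", "PP3")))
  add("revel_0.70_neutral", v_out("fx_r70"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.70,
                        splice_score = 0.5),
      exp_("VUS", 1L, "PM2"))
  add("revel_0.40_neutral", v_out("fx_r40"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.40,
                        splice_score = 0.5),
      exp_("VUS", 1L, "PM2"))
  add("revel_0.39_bp4", v_out("fx_r39"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.39,
                        splice_score = 0.5),
      exp_("LBV", -1L, c("BP4", "PM2"), "pm2_excluded"))

  # splice guard for BP1 (outside domains)
  add("splice_0.19_bp1", v_out("fx_s19"),
      annotation_bundle(allele_count = 0L, allele_number = an,
                        splice_score = 0.19),
      exp_("LBV", -1L, c("BP1", "PM2"), "pm2_excluded"))
  add("splice_0.20_blocked", v_out("fx_s20"),
      annotation_bundle(allele_count = 0L, allele_number = an,
                        splice_score = 0.20),
      exp_("VUS", 1L, "PM2"))

  # odds-ratio boundary (inclusive at 10)
  add("or_10_ps4", v_out("fx_or10"),
      annotation_bundle(allele_count = 0L, allele_number = an,
                        splice_score = 0.5, case_control_or = 10),
      exp_("VUS", 5L, c("PM2", "PS4")))
  add("or_9.9_no_ps4", v_out("fx_or99"),
      annotation_bundle(allele_count = 0L, allele_number = an,
                        splice_score = 0.5, case_control_or = 9.9),
      exp_("VUS", 1L, "PM2"))

  # allele counts one either side of the BS1 / BA1 tolerances
  add("ac_at_bs1_tolerance_pm2", v_out("fx_bs1lo"),
      annotation_bundle(allele_count = bs1_tol, allele_number = an,
                        splice_score = 0.5),
      exp_("VUS", 1L, "PM2"))
  add("ac_above_bs1_tolerance", v_out("fx_bs1hi"),
      annotation_bundle(allele_count = bs1_tol + 1L, allele_number = an,
                        splice_score = 0.5),
      exp_("LBV", -4L, "BS1"))
  add("ac_at_ba1_tolerance_bs1", v_out("fx_ba1lo"),
      annotation_bundle(allele_count = ba1_tol, allele_number = an,
                        splice_score = 0.5),
      exp_("LBV", -4L, "BS1"))
  add("ac_above_ba1_tolerance", v_out("fx_ba1hi"),
      annotation_bundle(allele_count = ba1_tol + 1L, allele_number = an,
                        splice_score = 0.5),
      exp_("BV", -8L, "BA1", "ba1_standalone"))

  # point totals at every category cut (gene-specific engine)
  add("total_10_pv", v_out("fx_t10"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.85,
                        splice_score = 0.5, functional_result = "abnormal",
                        assay_strength = "strong", case_control_or = 12),
      exp_("PV", 10L, c("PM2", "PP3", "PS3", "PS4")))
  add("total_9_lpv", v_ring("fx_t9"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.85,
                        functional_result = "abnormal",
                        assay_strength = "strong",
                        same_residue_refs = same_residue_ref(
                          "p.Xaa50Yaa", "PV", revel = 0.80)),
      exp_("LPV", 9L, c("PM1", "PM2", "PM5", "PP3", "PS3")))
  add("total_6_lpv", v_out("fx_t6"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.75,
                        splice_score = 0.5, functional_result = "abnormal",
                        assay_strength = "strong"),
      exp_("LPV", 6L, c("PM2", "PP3", "PS3")))
  add("total_5_vus", v_out("fx_t5"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.5,
                        splice_score = 0.5, case_control_or = 10),
      exp_("VUS", 5L, c("PM2", "PS4")))
  add("total_0_vus", v_ring("fx_t0"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.3,
                        multifactorial_lr = 0.3),
      exp_("VUS", 0L, c("BP4", "BP6", "PM1", "PM2")))
  add("total_-1_lbv", v_out("fx_tm1"),
      annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.3,
                        splice_score = 0.5),
      exp_("LBV", -1L, c("BP4", "PM2"), "pm2_excluded"))
  add("total_-5_lbv", v_out("fx_tm5"),
      annotation_bundle(allele_count = bs1_tol + 1L, allele_number = an,
                        revel = 0.3, splice_score = 0.5),
      exp_("LBV", -5L, c("BP4", "BS1")))
  add("total_-6_divergence", v_out("fx_tm6"),
      annotation_bundle(allele_count = bs1_tol + 1L, allele_number = an,
                        revel = 0.30, metarnn = 0.30, splice_score = NA_real_),
      exp_("BV", -6L, c("BP1", "BP4", "BS1")),
      auto = exp_("LBV", -6L, c("BP1", "BP4", "BS1")))
  add("total_-7_bv", v_out("fx_tm7"),
      annotation_bundle(allele_count = bs1_tol + 1L, allele_number = an,
                        revel = 0.3, splice_score = 0.05,
                        multifactorial_lr = 0.4),
      exp_("BV", -7L, c("BP1", "BP4", "BP6", "BS1")))
  fx
}
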