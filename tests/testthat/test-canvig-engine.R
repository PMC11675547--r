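cfg <- canvig_config()
an <- 100000L

test_that("population evidence picks exactly one of BA1, BS1, PM2", {
  # far above the BA1 tolerance
  e <- assess_population(annotation_bundle(af = 0.002, allele_count = 200L,
                                           allele_number = an), cfg)
  expect_identical(e$code, "BA1")
  expect_identical(e$strength, "standalone")
  # absence from controls
  e <- assess_population(annotation_bundle(allele_count = 0L,
                                           allele_number = an), cfg)
  expect_identical(e$code, "PM2")
  expect_identical(e$strength, "supporting")
  # exactly at the BS1 tolerance: strict-exceed rule keeps PM2
  tol <- max_tolerated_allele_count(cfg$freq$bs1_af, an)
  e <- assess_population(annotation_bundle(allele_count = tol,
                                           allele_number = an), cfg)
  expect_identical(e$code, "PM2")
  e <- assess_population(annotation_bundle(allele_count = tol + 1L,
                                           allele_number = an), cfg)
  expect_identical(e$code, "BS1")
  # no count data at all: PM2 path, never benign
  e <- assess_population(annotation_bundle(), cfg)
  expect_identical(e$code, "PM2")
  # config switch: absence at moderate
  cfg2 <- canvig_config(pm2_absent_strength = "moderate")
  e <- assess_population(annotation_bundle(allele_count = 0L,
                                           allele_number = an), cfg2)
  expect_identical(e$strength, "moderate")
})

test_that("functional evidence maps assay results to PS3/BS3 at assay strength", {
  e <- assess_functional(annotation_bundle(functional_result = "abnormal",
                                           assay_strength = "strong"), cfg)
  expect_identical(e$code, "PS3")
  expect_equal(e$points, 4L)
  e <- assess_functional(annotation_bundle(functional_result = "normal",
                                           assay_strength = "strong"), cfg)
  expect_identical(e$code, "BS3")
  expect_equal(e$points, -4L)
  e <- assess_functional(annotation_bundle(functional_result = "splice_effect",
                                           assay_strength = "moderate"), cfg)
  expect_identical(e$code, "PS3")
  expect_identical(e$note, "splice_effect")
  expect_equal(nrow(assess_functional(
    annotation_bundle(functional_result = "intermediate",
                      assay_strength = "strong"), cfg)), 0L)
  expect_equal(nrow(assess_functional(annotation_bundle(), cfg)), 0L)
  expect_error(assess_functional(
    annotation_bundle(functional_result = "abnormal"), cfg,
    variant_id = "v42"), "v42")
})

test_that("PM5 strength follows the REVEL comparison and reference status", {
  v <- variant_record("v", protein_position = 1700)
  # equivalent or more deleterious: moderate
  b <- annotation_bundle(revel = 0.85,
                         same_residue_refs = same_residue_ref("p.X", "PV",
                                                              revel = 0.80))
  e <- assess_same_residue(v, b, cfg)
  expect_identical(e$strength, "moderate")
  # less deleterious: supporting
  b <- annotation_bundle(revel = 0.60,
                         same_residue_refs = same_residue_ref("p.X", "PV",
                                                              revel = 0.80))
  expect_identical(assess_same_residue(v, b, cfg)$strength, "supporting")
  # LPV with limited reports: supporting even when more deleterious
  b <- annotation_bundle(revel = 0.95,
                         same_residue_refs = same_residue_ref(
                           "p.X", "LPV", revel = 0.80,
                           limited_reports = TRUE))
  expect_identical(assess_same_residue(v, b, cfg)$strength, "supporting")
  # strongest applicable across several references, one PM5 only
  b <- annotation_bundle(revel = 0.85, same_residue_refs = rbind(
    same_residue_ref("p.X", "LPV", revel = 0.9, limited_reports = TRUE),
    same_residue_ref("p.Y", "PV", revel = 0.80)))
  e <- assess_same_residue(v, b, cfg)
  expect_equal(nrow(e), 1L)
  expect_identical(e$strength, "moderate")
  # no references: no PM5
  expect_equal(nrow(assess_same_residue(v, annotation_bundle(), cfg)), 0L)
})

test_that("multifactorial likelihood ratios map through the monotone bins", {
  lr_case <- function(lr) assess_multifactorial(
    annotation_bundle(multifactorial_lr = lr), cfg)
  expect_equal(nrow(lr_case(1)), 0L)           # neutral
  expect_equal(nrow(lr_case(1.5)), 0L)         # inside neutral band
  expect_identical(lr_case(2.5)$strength, "supporting")
  expect_identical(lr_case(5)$strength, "moderate")
  expect_identical(lr_case(20)$strength, "strong")
  e <- lr_case(400)
  expect_identical(e$code, "PP5")
  expect_identical(e$strength, "very_strong")
  expect_equal(e$points, 8L)
  e <- lr_case(0.45)
  expect_identical(e$code, "BP6")
  expect_identical(e$strength, "supporting")
  expect_equal(e$points, -1L)
  expect_identical(lr_case(0.04)$strength, "strong")  # capped at strong
  expect_error(lr_case(-2), "positive")
  expect_error(lr_case(0), "positive")
})

test_that("REVEL thresholds for PP3/BP4 are strict on both sides", {
  rv <- function(r) assess_insilico(annotation_bundle(revel = r), cfg)
  expect_identical(rv(0.71)$code, "PP3")
  expect_equal(nrow(rv(0.70)), 0L)
  expect_equal(nrow(rv(0.40)), 0L)
  expect_identical(rv(0.39)$code, "BP4")
  expect_equal(nrow(assess_insilico(annotation_bundle(), cfg)), 0L)
})

test_that("location evidence distinguishes domains, splice guard and residues", {
  at <- function(pos, splice = NA_real_, cfg. = cfg)
    assess_location(variant_record("v", protein_position = pos),
                    annotation_bundle(splice_score = splice), cfg.)
  expect_identical(at(50)$code, "PM1")         # RING 1..101
  expect_identical(at(1400)$note, "COILED-COIL")
  expect_identical(at(1700)$note, "BRCT")
  expect_identical(at(1200, 0.05)$code, "BP1") # outside, no splice effect
  expect_equal(nrow(at(1200, 0.5)), 0L)        # splice guard blocks BP1
  expect_equal(nrow(at(1200, 0.2)), 0L)        # guard is inclusive at 0.2
  expect_identical(at(1200)$code, "BP1")       # absent score allowed
  cfg_block <- canvig_config(bp1_when_splice_absent = FALSE)
  expect_equal(nrow(at(1200, cfg. = cfg_block)), 0L)
  cfg_res <- canvig_config(pm1_moderate_residues = 50L)
  expect_identical(at(50, cfg. = cfg_res)$strength, "moderate")
  expect_identical(at(51, cfg. = cfg_res)$strength, "supporting")
})

test_that("case-control enrichment applies PS4 at the inclusive OR threshold", {
  oc <- function(or) assess_case_control(
    annotation_bundle(case_control_or = or), cfg)
  expect_identical(oc(12)$code, "PS4")
  expect_identical(oc(10)$code, "PS4")
  expect_equal(oc(10)$points, 4L)
  expect_equal(nrow(oc(9.9)), 0L)
  expect_equal(nrow(assess_case_control(annotation_bundle(), cfg)), 0L)
  expect_error(oc(-1), "positive")
})

test_that("combination applies thresholds, PM2 exclusion and VUS override", {
  # printed-threshold arithmetic
  r <- combine_canvig(evidence_table(evidence("PS3", "strong"),
                                     evidence("PM2", "supporting"),
                                     evidence("PP3", "supporting")), cfg)
  expect_identical(r$category, "LPV")
  expect_equal(r$total_points, 6L)
  expect_length(r$overrides_applied, 0L)
  # PM2 exclusion when it is the sole pathogenic element
  r <- combine_canvig(evidence_table(evidence("PM2", "supporting"),
                                     evidence("BP4", "supporting")), cfg)
  expect_identical(r$category, "LBV")
  expect_equal(r$total_points, -1L)
  expect_identical(r$overrides_applied, "pm2_excluded")
  # VUS override: benign total but two pathogenic elements
  r <- combine_canvig(evidence_table(evidence("PP3", "supporting"),
                                     evidence("PM1", "supporting"),
                                     evidence("BS3", "strong")), cfg)
  expect_identical(r$category, "VUS")
  expect_equal(r$total_points, -2L)
  expect_identical(r$overrides_applied, "vus_override")
  # BA1 stand-alone forces BV
  r <- combine_canvig(evidence_table(evidence("BA1", "standalone"),
                                     evidence("PP3", "supporting")), cfg)
  expect_identical(r$category, "BV")
  expect_identical(r$overrides_applied, "ba1_standalone")
  # duplicates rejected
  expect_error(combine_canvig(evidence_table(evidence("PP3", "supporting"),
                                             evidence("PP3", "supporting")),
                              cfg), "duplicate")
})

test_that("category boundaries land on the printed cut-points", {
  totals <- c(`10` = "PV", `9` = "LPV", `6` = "LPV", `5` = "VUS",
              `0` = "VUS", `-1` = "LBV", `-5` = "LBV", `-6` = "BV")
  for (t in names(totals))
    expect_identical(map_category(as.integer(t), cfg$thresholds),
                     unname(totals[t]), label = paste("total", t))
})

test_that("whole-variant classification is deterministic and order-independent", {
  v <- variant_record("v1", protein_position = 55)
  b <- annotation_bundle(allele_count = 0L, allele_number = an, revel = 0.8,
                         functional_result = "abnormal",
                         assay_strength = "moderate",
                         multifactorial_lr = 5)
  r1 <- classify_variant_canvig(v, b, cfg)
  r2 <- classify_variant_canvig(v, b, cfg)
  expect_identical(r1, r2)
  expect_identical(r1$evidence$code, sort(r1$evidence$code))
  # empty bundle scores 1 through PM2-absent and stays VUS
  r <- classify_variant_canvig(variant_record("v2", protein_position = 1200),
                               annotation_bundle(splice_score = 0.5), cfg)
  expect_identical(r$category, "VUS")
  expect_equal(r$total_points, 1L)
  # non-missense rejected
  expect_error(classify_variant_canvig(
    variant_record("v3", protein_position = 5, consequence = "other"),
    annotation_bundle(), cfg), "missense")
})

test_that("adding pathogenic evidence never moves the category toward benign", {
  rank3 <- c(B_LB = 1L, VUS = 2L, P_LP = 3L)
  base_pool <- list(evidence("PM2", "supporting"), evidence("BP4", "supporting"),
                    evidence("BS3", "strong"), evidence("BP1", "supporting"))
  extras <- list(evidence("PS3", "strong"), evidence("PP3", "supporting"),
                 evidence("PM1", "moderate"))
  for (k in 0:(2^length(base_pool) - 1)) {
    sel <- as.logical(bitwAnd(k, 2^(seq_along(base_pool) - 1)))
    evid <- evidence_table(base_pool[sel])
    before <- consolidate(combine_canvig(evid, cfg)$category)
    for (ex in extras) {
      after <- consolidate(
        combine_canvig(evidence_table(c(base_pool[sel], list(ex))),
                       cfg)$category)
      expect_gte(rank3[after], rank3[before])
    }
  }
})
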