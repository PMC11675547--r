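test_that("confusion-matrix marginals conserve tier counts (exhaustive n <= 4)", {
  tiers <- vc_tiers3()
  for (n in 1:4) {
    grids <- expand.grid(rep(list(seq_len(3)), 2 * n))
    # subsample the larger grids to keep the loop quick but exhaustive at n<=2
    if (n <= 2) idx <- seq_len(nrow(grids))
    else idx <- seq(1, nrow(grids), by = max(1L, nrow(grids) %/% 200L))
    for (i in idx) {
      a <- tiers[as.integer(grids[i, 1:n])]
      b <- tiers[as.integer(grids[i, (n + 1):(2 * n)])]
      m <- build_confusion(a, b)
      expect_identical(unname(attr(m, "row_totals")),
                       unname(vapply(tiers, function(t) sum(a == t),
                                     numeric(1))))
      expect_identical(unname(attr(m, "col_totals")),
                       unname(vapply(tiers, function(t) sum(b == t),
                                     numeric(1))))
      expect_identical(attr(m, "grand_total"), n)
    }
  }
})

test_that("confusion construction validates alignment and labels", {
  m <- build_confusion("P_LP", "B_LB")
  expect_equal(unclass(m)["P_LP", "B_LB"], 1L, ignore_attr = TRUE)
  expect_equal(sum(unclass(m)), 1L)
  expect_error(build_confusion(c("P_LP", "VUS"), "P_LP"), "not aligned")
  expect_error(build_confusion("P_LP", "pathogenic"), "unknown tier")
})

test_that("concordance equals direct pairwise agreement with exact CI", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    a <- sample(vc_tiers3(), n, replace = TRUE)
    b <- sample(vc_tiers3(), n, replace = TRUE)
    agr <- concordance_rate(build_confusion(a, b))
    expect_equal(agr$concordance, mean(a == b))
    ci <- oracle_clopper_pearson(sum(a == b), n)
    expect_equal(agr$ci_low, ci[1], tolerance = 1e-10)
    expect_equal(agr$ci_high, ci[2], tolerance = 1e-10)
  }
  # degenerate cases
  m <- build_confusion(rep("VUS", 3), rep("VUS", 3))
  agr <- concordance_rate(m)
  expect_equal(agr$concordance, 1)
  expect_equal(agr$ci_high, 1)
  agr <- concordance_rate(build_confusion(c("P_LP", "VUS"), c("P_LP", "B_LB")))
  expect_equal(agr$concordance, 0.5)
  expect_equal(c(agr$ci_low, agr$ci_high), oracle_clopper_pearson(1, 2),
               tolerance = 1e-10)
})

test_that("distribution percentages use one-decimal half-away rounding and sum to ~100", {
  expect_equal(percent_of(232, 450), 51.6)
  expect_equal(percent_of(19, 21), 90.5)
  expect_equal(percent_of(45, 400), 11.3)  # exact half rounds away from zero
  d <- classification_distribution(c(rep("P_LP", 1), rep("VUS", 0),
                                     rep("B_LB", 0)))
  expect_equal(d$percent[d$tier == "P_LP"], 100.0)
  set.seed(7)
  for (rep in 1:10) {
    tiers <- sample(vc_tiers3(), sample(3:200, 1), replace = TRUE)
    d <- classification_distribution(tiers)
    expect_equal(sum(d$count), length(tiers))
    expect_lte(abs(sum(d$percent) - 100), 0.1)
  }
  # five-tier input is consolidated first
  d <- classification_distribution(c("PV", "LPV", "VUS", "BV"))
  expect_equal(d$count, c(2L, 1L, 1L))
})

test_that("stratified agreement splits majority / minority / any correctly", {
  make_set <- function(cls, vid) structure(list(
    variant = variant_record(vid, protein_position = 10),
    submissions = data.frame(
      submitter_id = paste0("s", seq_along(cls)), classification = cls,
      assertion_criteria = TRUE, snapshot_date = "x",
      stringsAsFactors = FALSE)), class = "vc_submission_set")
  sets <- list(
    make_set(c("PV", "PV", "VUS"), "a"),   # 2/3 P_LP: majority
    make_set(c("PV", "VUS", "VUS"), "b"),  # 1/3 P_LP: minority
    make_set(c("VUS", "BV"), "c")          # 0 P_LP: neither
  )
  engine <- c("P_LP", "VUS", "B_LB")
  rep_ <- stratified_agreement(engine, sets, "P_LP")
  expect_identical(rep_$stratum, c("majority", "minority", "any"))
  expect_equal(rep_$n, c(1L, 1L, 2L))
  expect_equal(rep_$matches, c(1L, 0L, 1L))
  expect_equal(rep_$percent, c(100.0, 0.0, 50.0))
  # a tier nobody asserted: all strata empty, proportion undefined
  none <- stratified_agreement(engine[1:2],
                               list(make_set(c("VUS", "VUS"), "d"),
                                    make_set(c("VUS", "VUS"), "e")),
                               "B_LB")
  expect_equal(none$n, c(0L, 0L, 0L))
  expect_true(all(is.na(none$percent)))
  expect_error(stratified_agreement(engine[1:2], sets, "P_LP"),
               "not aligned")
})

test_that("consensus comparison restricts, tallies and lists mismatches", {
  engine <- c("P_LP", "VUS", "B_LB", "VUS")
  cons <- c("P_LP", NA, "B_LB", "P_LP")
  cmp <- consensus_comparison(engine, cons, c("a", "b", "c", "d"))
  expect_equal(cmp$n_total, 4L)
  expect_equal(cmp$n_consensus, 3L)
  expect_equal(unname(cmp$tier_counts), c(2L, 0L, 1L))
  expect_equal(nrow(cmp$mismatches), 1L)
  expect_identical(cmp$mismatches$variant_id, "d")
  expect_identical(cmp$mismatches$engine_tier, "VUS")
  expect_identical(cmp$mismatches$consensus_tier, "P_LP")
  # identical classifications: empty mismatch list
  cmp <- consensus_comparison(engine, engine)
  expect_equal(nrow(cmp$mismatches), 0L)
  expect_equal(cmp$n_consensus, 4L)
})
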