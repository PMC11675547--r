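# build a small submission TSV in code
write_fixture_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste(submission_columns(), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

row_tsv <- function(vid, pos, cons, sub, cls, ac = "true",
                    date = "2022-12-20") {
  paste(vid, "BRCA1", "c.?", "p.?", pos, cons, sub, cls, ac, date,
        sep = "\t")
}

test_that("parsing groups rows by variant and normalises labels", {
  path <- write_fixture_tsv(c(
    row_tsv("v1", 50, "missense", "s1", "Pathogenic"),
    row_tsv("v1", 50, "missense", "s2", "likely pathogenic"),
    row_tsv("v1", 50, "missense", "s3", "Uncertain significance"),
    row_tsv("v2", 700, "missense", "s1", "Benign")
  ))
  sets <- parse_submission_table(path)
  expect_length(sets, 2L)
  expect_equal(nrow(sets[[1]]$submissions), 3L)
  expect_identical(sets[[1]]$submissions$classification,
                   c("PV", "LPV", "VUS"))
  expect_identical(sets[[2]]$variant$variant_id, "v2")
  expect_equal(nrow(attr(sets, "errors")), 0L)
})

test_that("malformed rows are reported with line numbers, not fatal", {
  path <- write_fixture_tsv(c(
    row_tsv("v1", 50, "missense", "s1", "Pathogenic"),
    row_tsv("v1", 50, "missense", "s2", "mystery label"),
    row_tsv("v3", -4, "missense", "s1", "Benign")
  ))
  sets <- parse_submission_table(path)
  err <- attr(sets, "errors")
  expect_equal(nrow(err), 2L)
  expect_setequal(err$line, c(3L, 4L))   # header is line 1
  expect_setequal(err$problem,
                  c("unknown classification label", "invalid protein_position"))
  expect_length(sets, 1L)
})

test_that("missing columns and empty files are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("variant_id\tgene\thgvs_c", path)
  expect_error(parse_submission_table(path), "hgvs_p")
  path2 <- write_fixture_tsv(character())
  expect_length(parse_submission_table(path2), 0L)
  expect_error(parse_submission_table("/no/such/file.tsv"), "no such file")
})

make_set <- function(cls, ac = rep(TRUE, length(cls)), cons = "missense",
                     vid = "v1") {
  structure(list(
    variant = variant_record(vid, protein_position = 10, consequence = cons),
    submissions = data.frame(
      submitter_id = paste0("s", seq_along(cls)), classification = cls,
      assertion_criteria = ac, snapshot_date = "2022-12-20",
      stringsAsFactors = FALSE)),
    class = "vc_submission_set")
}

test_that("conflict means two countable submissions in two consolidated tiers", {
  expect_true(is_conflicting(make_set(c("PV", "VUS"))))
  expect_false(is_conflicting(make_set(c("PV", "LPV"))))   # same tier
  expect_false(is_conflicting(make_set("VUS")))            # one submitter
  expect_false(is_conflicting(make_set(c("BV", "LBV"))))
  # assertion-criteria filtering: the conflicting submission does not count
  expect_false(is_conflicting(make_set(c("PV", "VUS", "PV"),
                                       ac = c(TRUE, FALSE, TRUE))))
  expect_true(is_conflicting(make_set(c("PV", "VUS", "PV"),
                                      ac = c(TRUE, TRUE, FALSE))))
})

test_that("conflicting-missense selection filters and is idempotent", {
  sets <- list(
    make_set(c("PV", "VUS"), vid = "a"),                 # keep
    make_set(c("PV", "VUS"), cons = "other", vid = "b"), # non-missense
    make_set(c("PV", "LPV"), vid = "c"),                 # not conflicting
    make_set(c("VUS", "BV"), vid = "d")                  # keep
  )
  kept <- select_conflicting_missense(sets)
  expect_identical(vapply(kept, function(s) s$variant$variant_id,
                          character(1)), c("a", "d"))
  expect_identical(select_conflicting_missense(kept), kept)
  expect_length(select_conflicting_missense(list()), 0L)
})

test_that("submitter tier fractions count assertion-criteria submissions only", {
  s <- make_set(c("PV", "LPV", "VUS"))
  expect_equal(submitter_tier_fraction(s, "P_LP"), 2 / 3)
  expect_equal(submitter_tier_fraction(s, "B_LB"), 0)
  # fractions over the three tiers always sum to 1
  sets <- list(make_set(c("PV", "VUS", "BV", "LBV")),
               make_set(c("VUS", "VUS")),
               make_set(c("PV", "BV"), ac = c(TRUE, TRUE)))
  for (s in sets) {
    tot <- sum(vapply(vc_tiers3(), function(t)
      submitter_tier_fraction(s, t), numeric(1)))
    expect_equal(tot, 1)
  }
  expect_error(submitter_tier_fraction(
    make_set(c("PV", "VUS"), ac = c(FALSE, FALSE)), "P_LP"),
    "no countable")
})

test_that("consensus detection agrees with the conflict predicate", {
  expect_identical(detect_consensus(make_set(c("LPV", "PV"))), "P_LP")
  expect_identical(detect_consensus(make_set(c("BV", "BV", "LBV"))), "B_LB")
  expect_true(is.na(detect_consensus(make_set(c("LBV", "VUS")))))
  # property: consensus is NA exactly when the countable subset conflicts
  cases <- list(c("PV", "VUS"), c("PV", "LPV"), c("VUS"), c("BV", "LBV"),
                c("PV", "BV"), c("VUS", "VUS", "LBV"))
  for (cls in cases) {
    s <- make_set(cls)
    expect_identical(is.na(detect_consensus(s)), is_conflicting(s))
  }
})
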