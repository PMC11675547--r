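# Pipeline plumbing: cohort-level classification, TSV serialisation of the
# cohort dialects, and a staged runner (simulate / classify / compare /
# consensus) that records a manifest with every output.

#' Classify every variant of a cohort with one engine
#'
#' @param variants List of [variant_record()] objects.
#' @param bundles List of [annotation_bundle()] objects, aligned.
#' @param engine `"canvig"` or `"auto"`.
#' @param cfg Engine config; defaults to the engine's default config.
#' @return Data frame with one row per variant: `variant_id`, `engine`,
#'   `category`, `tier`, `total_points`, `n_evidence`, `codes`,
#'   `overrides`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_variants = 4, seed = 2))
#' classify_cohort(cohort$variants, cohort$bundles, "canvig")
#' @export
classify_cohort <- function(variants, bundles, engine = c("canvig", "auto"),
                            cfg = NULL) {
  engine <- match.arg(engine)
  if (length(variants) != length(bundles))
    stop("variants and bundles are not aligned", call. = FALSE)
  if (is.null(cfg))
    cfg <- if (engine == "canvig") canvig_config() else auto_config()
  classify <- if (engine == "canvig") classify_variant_canvig
              else classify_variant_auto
  rows <- lapply(seq_along(variants), function(i)
    summary(classify(variants[[i]], bundles[[i]], cfg)))
  do.call(rbind, rows)
}

serialize_refs <- function(refs) {
  if (is.null(refs) || nrow(refs) == 0L) return("")
  paste(sprintf("%s|%s|%s|%d", refs$hgvs_p, refs$classification,
                ifelse(is.na(refs$revel), "NA", format(refs$revel)),
                as.integer(refs$limited_reports)),
        collapse = ";")
}

parse_refs <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    if (length(p) != 4L)
      stop("malformed same-residue reference field: ", s, call. = FALSE)
    same_residue_ref(p[1], p[2], suppressWarnings(as.numeric(p[3])),
                     as.integer(p[4]) == 1L)
  }))
}

#' Write / read the per-variant annotation TSV dialect
#'
#' One row per variant with the bundle fields; same-residue references are
#' packed into a single `same_residue_refs` column as
#' `hgvs_p|classification|revel|limited;...`.
#'
#' @param variants,bundles Aligned lists.
#' @param path TSV path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns a list with `variants` and `bundles`.
#' @export
write_annotations <- function(variants, bundles, path) {
  df <- do.call(rbind, lapply(seq_along(variants), function(i) {
    v <- variants[[i]]; b <- bundles[[i]]
    data.frame(
      variant_id = v$variant_id, gene = v$gene, hgvs_c = v$hgvs_c,
      hgvs_p = v$hgvs_p, protein_position = v$protein_position,
      consequence = v$consequence,
      af = b$af, allele_count = b$allele_count,
      allele_number = b$allele_number, revel = b$revel,
      metarnn = b$metarnn, splice_score = b$splice_score,
      functional_result = b$functional_result,
      assay_strength = b$assay_strength,
      multifactorial_lr = b$multifactorial_lr,
      case_control_or = b$case_control_or,
      same_residue_refs = serialize_refs(b$same_residue_refs),
      same_aa_pathogenic = b$same_aa_pathogenic,
      repeat_region = b$repeat_region,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @param path TSV path.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("variant_id", "protein_position", "consequence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(col) if (col %in% names(df)) as.numeric(df[[col]])
         else rep(NA_real_, nrow(df))
  chr <- function(col, default = NA_character_)
    if (col %in% names(df)) as.character(df[[col]])
    else rep(default, nrow(df))
  lgl <- function(col) if (col %in% names(df)) as.logical(df[[col]])
         else rep(FALSE, nrow(df))
  variants <- vector("list", nrow(df))
  bundles <- vector("list", nrow(df))
  fun <- chr("functional_result", "none")
  fun[is.na(fun)] <- "none"
  for (i in seq_len(nrow(df))) {
    variants[[i]] <- variant_record(
      df$variant_id[i], gene = chr("gene")[i], hgvs_c = chr("hgvs_c")[i],
      hgvs_p = chr("hgvs_p")[i],
      protein_position = df$protein_position[i],
      consequence = df$consequence[i])
    bundles[[i]] <- annotation_bundle(
      af = num("af")[i],
      allele_count = num("allele_count")[i],
      allele_number = num("allele_number")[i],
      revel = num("revel")[i], metarnn = num("metarnn")[i],
      splice_score = num("splice_score")[i],
      functional_result = fun[i],
      assay_strength = chr("assay_strength")[i],
      multifactorial_lr = num("multifactorial_lr")[i],
      case_control_or = num("case_control_or")[i],
      same_residue_refs = parse_refs(chr("same_residue_refs")[i]),
      same_aa_pathogenic = isTRUE(lgl("same_aa_pathogenic")[i]),
      repeat_region = isTRUE(lgl("repeat_region")[i]))
  }
  list(variants = variants, bundles = bundles)
}

#' Write submission sets in the ClinVar-style TSV dialect
#'
#' @param sets List of `vc_submission_set` objects.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_submissions <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    v <- s$variant
    cbind(data.frame(variant_id = v$variant_id, gene = v$gene,
                     hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p,
                     protein_position = v$protein_position,
                     consequence = v$consequence,
                     stringsAsFactors = FALSE),
          s$submissions)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, command, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("varconcord")),
    seed = seed, inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Staged command-line-style runner over the package's functions:
#' \describe{
#'   \item{`simulate`}{generate a seeded cohort and write the variant,
#'     annotation and two-snapshot submission TSVs.}
#'   \item{`classify`}{read annotations and write per-variant
#'     classifications for one or both engines.}
#'   \item{`compare`}{read two engine classification TSVs, write the
#'     per-engine tier distributions, the 3x3 confusion matrix and the
#'     concordance report.}
#'   \item{`consensus`}{read an engine classification TSV plus a
#'     later-snapshot submission TSV and write the consensus-update
#'     comparison.}
#' }
#' Every stage writes a JSON manifest (`manifest_<command>.json`) recording
#' command, seed, inputs and outputs.
#'
#' @param command One of `"simulate"`, `"classify"`, `"compare"`,
#'   `"consensus"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for `simulate`.
#' @param n_variants Cohort size for `simulate`.
#' @param annotations Annotation TSV path (`classify`).
#' @param engine `"canvig"`, `"auto"` or `"both"` (`classify`).
#' @param classifications_a,classifications_b Classification TSV paths
#'   (`compare`: A then B; `consensus` uses `classifications_a`).
#' @param submissions Later-snapshot submission TSV path (`consensus`).
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "classify", "compare",
                                     "consensus"),
                         out_dir = ".", seed = 1L, n_variants = 450L,
                         annotations = NULL, engine = "both",
                         classifications_a = NULL, classifications_b = NULL,
                         submissions = NULL) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out[[name]] <<- p
    p
  }

  if (command == "simulate") {
    cohort <- generate_cohort(cohort_spec(n_variants = n_variants,
                                          seed = seed))
    out[["annotations.tsv"]] <- write_annotations(
      cohort$variants, cohort$bundles, file.path(out_dir, "annotations.tsv"))
    out[["submissions_t1.tsv"]] <- write_submissions(
      cohort$sets_t1, file.path(out_dir, "submissions_t1.tsv"))
    out[["submissions_t2.tsv"]] <- write_submissions(
      cohort$sets_t2, file.path(out_dir, "submissions_t2.tsv"))
    write_manifest(out_dir, command, seed, list(), as.list(out))
    return(invisible(out))
  }

  if (command == "classify") {
    if (is.null(annotations))
      stop("classify requires an annotations TSV", call. = FALSE)
    inp <- read_annotations(annotations)
    engines <- if (engine == "both") c("canvig", "auto") else engine
    for (e in engines)
      w(classify_cohort(inp$variants, inp$bundles, e),
        paste0("classifications_", e, ".tsv"))
    write_manifest(out_dir, command, seed,
                   list(annotations = annotations), as.list(out))
    return(invisible(out))
  }

  if (command == "compare") {
    if (is.null(classifications_a) || is.null(classifications_b))
      stop("compare requires two classification TSVs", call. = FALSE)
    a <- utils::read.delim(classifications_a, stringsAsFactors = FALSE)
    b <- utils::read.delim(classifications_b, stringsAsFactors = FALSE)
    if (!identical(a$variant_id, b$variant_id))
      stop("classification tables are not aligned by variant", call. = FALSE)
    w(classification_distribution(a$tier), "distribution_a.tsv")
    w(classification_distribution(b$tier), "distribution_b.tsv")
    m <- build_confusion(a$tier, b$tier,
                         labels = c(a$engine[1L], b$engine[1L]))
    mdf <- as.data.frame.matrix(unclass(m)[, , drop = FALSE])
    mdf <- cbind(tier = rownames(mdf), mdf)
    w(mdf, "confusion.tsv")
    agr <- concordance_rate(m)
    rep <- data.frame(concordant = agr$concordant, n = agr$n,
                      concordance_percent = percent_of(agr$concordant, agr$n),
                      ci_low = agr$ci_low, ci_high = agr$ci_high)
    w(rep, "concordance.tsv")
    write_manifest(out_dir, command, seed,
                   list(a = classifications_a, b = classifications_b),
                   as.list(out))
    return(invisible(out))
  }

  # consensus
  if (is.null(classifications_a) || is.null(submissions))
    stop("consensus requires a classification TSV and a later-snapshot ",
         "submission TSV", call. = FALSE)
  cls <- utils::read.delim(classifications_a, stringsAsFactors = FALSE)
  sets <- parse_submission_table(submissions)
  ids <- vapply(sets, function(s) s$variant$variant_id, character(1))
  sets <- sets[match(cls$variant_id, ids)]
  if (anyNA(sapply(sets, is.null)) || any(sapply(sets, is.null)))
    stop("submission table does not cover all classified variants",
         call. = FALSE)
  cons <- vapply(sets, detect_consensus, character(1))
  cmp <- consensus_comparison(cls$tier, cons, cls$variant_id)
  w(data.frame(tier = names(cmp$tier_counts),
               consensus_count = as.integer(cmp$tier_counts)),
    "consensus_counts.tsv")
  w(cmp$mismatches, "consensus_mismatches.tsv")
  w(data.frame(n_total = cmp$n_total, n_consensus = cmp$n_consensus,
               consensus_fraction_percent = cmp$consensus_fraction_percent),
    "consensus_summary.tsv")
  write_manifest(out_dir, command, seed,
                 list(classifications = classifications_a,
                      submissions = submissions), as.list(out))
  invisible(out)
}
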