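Package: varconcord
Title: Points-Based ACMG/AMP Classification Engines and Concordance
    Analysis for Conflicting Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements two points-based ACMG/AMP variant classification
    engines for BRCA1 missense variants: a gene-specific engine following
    the CanVIG-UK guidance (population frequency tests with Poisson upper
    confidence bounds, functional assay evidence, same-residue comparison,
    multifactorial likelihood ratios, REVEL in-silico thresholds, domain
    location and case-control enrichment) and a generic automated engine
    emulating a VarSome-style point system driven by MetaRNN calibration
    bins.  Provides ingest of ClinVar-style submission tables, selection
    of variants with conflicting interpretations, three-tier consolidation,
    confusion-matrix concordance with exact binomial confidence intervals,
    submitter-stratified agreement, consensus-update comparison, and a
    seeded synthetic cohort generator so the full pipeline is testable
    without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
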