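---
title: "Methods: points-based classification engines and concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: points-based classification engines and concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconcord)
```

## The model

`varconcord` classifies *BRCA1* missense variants with a points-based
reading of the ACMG/AMP evidence framework. Every triggered evidence code
is an `(code, direction, strength)` triple carrying signed points —
supporting ±1, moderate ±2, strong ±4, very strong ±8, benign negative —
and a variant's category is a function of the summed total. Two engines
share this machinery:

* the **gene-specific engine** (`classify_variant_canvig()`), which models
  a CanVIG-UK-style gene-tailored assessment: population frequency against
  non-cancer female controls, graded functional assays, same-residue
  precedent, multifactorial likelihood ratios, REVEL, domain location and
  case-control enrichment, with threshold table PV ≥ 10 / LPV 6–9 /
  VUS 0–5 / LBV −5…−1 / BV ≤ −6 and two combination rules described below;
* the **generic automated engine** (`classify_variant_auto()`), which
  emulates a VarSome-style automatic point system: the same population
  test, MetaRNN calibration bins for computational evidence, and explicit
  toggles for automated behaviours, with threshold table PV ≥ 10 /
  LPV 6–9 / VUS 0–5 / LBV −6…−1 / BV ≤ −7.

The two threshold tables disagree only at a total of −6 (BV vs LBV), which
is why a −6-point variant is the canonical divergence case in the test
fixtures. The generic engine is an *emulation* of a described point system,
not a re-implementation of any proprietary rule set: every behaviour beyond
the basic point arithmetic is an explicit config toggle
(`apply_bp3_missense`, `apply_bp1_extended`, `allow_pm5_strong`,
`graded_bp4`, `functional_visible`).

### Combination rules (gene-specific engine)

`combine_canvig()` applies, in order:

1. **BA1 stand-alone.** If BA1 is present the variant is BV outright; the
   point total is still reported (BA1 carries −8 so totals stay
   well-defined) and the override is recorded as `ba1_standalone`.
2. **PM2 exclusion.** When PM2 is the *only* pathogenic-direction element
   and the total without it falls in benign territory (≤ −1), PM2 is
   dropped from the total (`pm2_excluded`). This implements "disregard PM2
   when benignity is strongly supported". We read "no additional
   pathogenicity-related evidence" as *PM2 is the sole pathogenic-direction
   element*; the alternative reading (count PM2 itself) would make the rule
   vacuous.
3. **VUS override.** If the mapped category is LBV or BV but two or more
   pathogenic-direction elements are present, the result is VUS
   (`vus_override`). Elements of any strength count, including
   supporting-only; requiring moderate-or-stronger would be a stricter
   reading, but the guidance ties the rule to the *number* of evidence
   elements, not their weight.

Evidence is canonically sorted by code before combination, so results are
independent of assessment order; duplicate codes are rejected rather than
de-duplicated, because a duplicate always indicates an upstream bug.

### The population test

BA1/BS1/PM2 use a maximum-tolerated allele-count test
(`max_tolerated_allele_count()`): the largest allele count compatible with
a frequency threshold is the one-sided 95% quantile of a Poisson
distribution with mean `AF_threshold × AN`, and only counts *strictly*
above it trigger the benign codes ("maximum tolerated" semantics). The
Poisson approximation to binomial allele-count sampling matches the
convention of the allele-frequency calculators used in cardiogenetics and
cancer genetics. The confidence level is one-sided: an upper bound on
plausible counts is what a filtering threshold needs, and the tooling this
reproduces uses the one-sided convention. Absent count data never yields
BA1/BS1 — benign frequency evidence requires observed data — and instead
takes the PM2 path as "absent from controls".

### Tunable parameters

| parameter | default | role |
|---|---|---|
| `ba1_af`, `bs1_af` | 0.001, 0.0001 | frequency thresholds (fractions) |
| `confidence` | 0.95 | one-sided Poisson level |
| `revel_pp3`, `revel_bp4` | 0.7, 0.4 | strict REVEL cuts for PP3/BP4 |
| `splice_bp1_max` | 0.2 | splice score at/above which BP1 is blocked |
| `ps4_or_min`, `ps4_strength` | 10, strong | case-control enrichment |
| domains | RING 1–101, COILED-COIL 1391–1424, BRCT 1650–1863 | PM1/BP1 geography |
| `pm1_moderate_residues` | empty | residues earning PM1 moderate |
| `lr_bins` | 2.08 / 4.33 / 18.7 / 350 (+ reciprocals) | PP5/BP6 strengths |
| `pm2_absent_strength` | supporting | PM2 grade for absence |
| `bp1_when_splice_absent` | TRUE | BP1 without a splice score |
| `metarnn_bins` | ≥0.70/0.85/0.94 path.; ≤0.40/0.20/0.05 benign | generic PP3/BP4 |

Design notes on the genuinely open choices:

* **Domain boundaries.** Two variants of the RING/BRCT boundaries are in
  circulation (RING from residue 1 vs 2; BRCT to 1863 vs 1857). The config
  defaults to the boundaries used in the assessment procedure (1–101,
  1650–1863); the alternative is one `canvig_config(domains = ...)` away.
* **Likelihood-ratio bins.** No published cut-offs accompany the PP5/BP6
  guidance, so the defaults are the Tavtigian-style odds-of-pathogenicity
  anchors (supporting 2.08, moderate 4.33, strong 18.7, very strong 350,
  reciprocals toward benign, benign capped at strong). They are config
  data, not constants.
* **MetaRNN calibration bins.** The generic tool's exact version-specific
  cut-offs are not public; the defaults are a graded supporting→strong
  mapping consistent with the observed "supporting to strong" weighting
  range, stored as config data.
* **PS4 strength.** The guidance allows very strong to supporting; with no
  printed modulation rule the default is strong, configurable.
* **PM2 for absence.** "Moderate to supporting" is printed without a
  trigger for moderate; the default is supporting everywhere with a
  `pm2_absent_strength = "moderate"` switch for absence.
* **PS1** fires only from an explicit input flag (an identical amino-acid
  change already classified pathogenic) at strong; no modulation rules are
  modelled because none are described.
* **BP1 with a missing splice score** is allowed by default (most cohort
  variants lack splice annotations; a missing prediction is treated as "no
  predicted effect"), blockable via config.

## Ingest, consolidation and concordance

The submission dialect is a simplified `variant_summary`-like TSV defined
by this package (one row per submitter assertion); free-text labels are
normalised case-insensitively (`"Likely pathogenic"` → `LPV`). Throughout
the analysis only assertion-criteria submissions count: the counting rule
for submitter tallies is extended to the conflict and consensus logic for
consistency. A variant *conflicts* when ≥ 2 countable submissions span
≥ 2 consolidated tiers — so PV-vs-LPV is not a conflict, matching the
consolidation into PV/LPV, VUS, BV/LBV used for every comparison. Whether
the original cohort selection tested conflicts before or after the
assertion-criteria restriction is not documented; the package filters
first, then tests.

Concordance is the trace of the 3×3 tier confusion matrix over its grand
total, with an exact Clopper–Pearson interval (`stats::binom.test`). The
interval printed alongside the original cohort's 58.9% (52.0–66.4%) is not
reproducible by standard binomial methods, so no test asserts it; the
package reports the exact interval instead. Percentages in all reports are
rounded to one decimal, half away from zero, which reproduces every printed
table value (e.g. 232/450 → 51.6). The discordant-cell counts of the
original comparison figure are internally inconsistent with its marginals
by one variant, so no reconstruction of the full matrix is asserted
anywhere; only the marginal arithmetic and the trace are used.

Stratified agreement reports three submitter strata per focal tier:
more than 50% of countable submitters asserting the tier, at most 50% but
at least one, and at least one (their union) — the "at least one submitter"
reading of the middle stratum is forced by the printed stratum sizes
(21 + 34 = 55).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, so every stage is exercisable end-to-end without downloads:

* positions concentrated in the RING and BRCT domains (default weights
  0.40/0.40, with 0.05 COILED-COIL and 0.15 elsewhere);
* submitter counts on 2–15 with elevated mass at 2, 3 and 5,
  proportioned to the observed 91/85/73-variant peaks;
* every first-snapshot set conflicting *by construction*
  (rejection-sampled tier assignments), so stage tests get fixed cohort
  sizes rather than post-hoc filtering losses;
* REVEL and MetaRNN drawn from a two-component (pathogenic-/benign-leaning)
  latent Gaussian model with correlation 0.7, reflecting that the two
  meta-predictors agree often but not always;
* zero-inflated allele frequencies (60% absent from controls; otherwise
  log-uniform on 10⁻⁶–10⁻³) against 50k–120k control alleles;
* sparse evidence availability (functional 15%, likelihood ratios 8%,
  odds ratios 5%, same-residue precedent 10%);
* a second snapshot in which 17/450 of variants resolve to a single-tier
  consensus.

What it does **not** emulate: real *BRCA1* mutational spectra or
trinucleotide context, gnomAD subpopulation structure, submitter-level
temporal dynamics, or any correlation between evidence axes beyond the
REVEL–MetaRNN pair. Passing pipeline tests on synthetic cohorts therefore
demonstrates the *bookkeeping* (determinism, conservation of counts,
conflict guarantees, format round-trips) and the engines' rule logic — not
that the synthetic tier distributions match any real cohort's.

`generate_boundary_fixtures()` complements the generator with hand-derived
fixtures at every decision boundary (REVEL 0.39/0.40/0.70/0.71, splice
0.19/0.20, OR 9.9/10, allele counts one either side of the BS1/BA1
tolerances, totals at −7, −6, −5, −1, 0, 5, 6, 9, 10); their expected
categories, totals and code sets are frozen in code.

## Numerical choices and degenerate inputs

* REVEL cuts are strict on both sides (0.70 and 0.40 exactly trigger
  nothing); the OR threshold is inclusive (OR = 10 triggers PS4); the
  splice guard is inclusive at 0.2 (a score of 0.2 blocks BP1); allele
  counts exactly at a tolerance do not exceed it.
* A likelihood ratio of exactly 1 is neutral; LR ≤ 0, OR ≤ 0 and scores
  outside [0, 1] are rejected, not clamped.
* An abnormal/normal functional result without an assay strength is an
  error naming the variant — silently defaulting a strength would alter
  point totals.
* An empty annotation bundle classifies as VUS (+1 via PM2-absent), and a
  wholly evidence-free combination is VUS at 0 points.
* Multiple same-residue references yield one PM5 at the strongest
  applicable grade; an LPV reference with limited reports is capped at
  supporting even when the query REVEL is higher.

## Verification strategy and problem sizes

The combiners are checked by exhaustive subset enumeration against a
brute-force oracle that restates the rules literally (two 6-element pools,
all 64 subsets each, both engines); the Poisson tolerance against
cumulative mass summation over a grid of 216 means up to 500; the
Clopper–Pearson interval against the beta-quantile closed form; confusion
marginals exhaustively for short inputs. Cohort-level properties use a
2,000-variant cohort for the submitter-distribution goodness-of-fit check
and a 450-variant cohort for the end-to-end determinism run — sizes chosen
to give the chi-square test power over all 14 submitter-count cells while
keeping the default suite quick to run.

## Limitations

* The engines operate on protein-level annotations; genomic coordinates,
  transcripts, splicing/indel codes (PVS1, PM4, BP7) and non-missense
  consequences are out of scope.
* The generic engine reproduces a described point system, not the internal
  triggers of any commercial tool or version.
* REVEL, MetaRNN and splice scores are inputs, never computed.
* Gene-specific functional-assay grading is taken as an input strength; the
  external assay-score tables it would come from are not reproduced.
* Population input is assumed already popmax-filtered; no subpopulation
  stratification is performed.
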