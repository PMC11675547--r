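# varconcord

Points-based ACMG/AMP classification engines and concordance analysis for
conflicting *BRCA1* missense variants.

## The problem

ClinVar aggregates variant classifications from many submitters, and the
same *BRCA1* missense variant is frequently labelled pathogenic by one
laboratory and benign or uncertain by another ("conflicting interpretations
of pathogenicity"). Resolving such conflicts requires re-interpreting each
variant under an explicit evidence framework. Two framework families are in
routine use: gene-specific guidance for *BRCA1/BRCA2* (CanVIG-UK style),
which weights functional assays, domain location and gene-tailored
population thresholds, and generic automated engines (VarSome style), which
score every gene with the same point system driven by computational
predictors.

`varconcord` implements both as transparent, configurable rule engines, plus
the surrounding analysis: ClinVar-style table ingest, conflict selection,
three-tier consolidation, confusion-matrix concordance, submitter-stratified
agreement, and consensus-update comparison. A seeded synthetic cohort
generator makes the full pipeline testable without any database downloads.

## The scoring model

Each triggered ACMG/AMP evidence code contributes signed points by strength
— supporting ±1, moderate ±2, strong ±4, very strong ±8 (benign negative) —
and the total maps to a five-tier category:

| total | gene-specific engine | generic engine |
|---|---|---|
| ≥ 10 | PV | PV |
| 6 … 9 | LPV | LPV |
| 0 … 5 | VUS | VUS |
| −5 … −1 | LBV | LBV (−6 … −1) |
| ≤ −6 | BV | BV (≤ −7) |

The only cut-point difference is a total of −6 (BV under the gene-specific
table, LBV under the generic one). The gene-specific engine adds two
combination rules: PM2 is excluded from the total when it is the sole
pathogenic-direction element and the remainder is in benign territory, and a
benign-range total with two or more pathogenic-direction elements is
returned as VUS. BA1 (common-variant frequency) is stand-alone: it forces BV
regardless of other evidence.

Population evidence (BA1/BS1/PM2) uses a maximum-tolerated allele-count
test: the observed gnomAD non-cancer female allele count must strictly
exceed the one-sided 95% Poisson quantile of `AF_threshold × AN` (thresholds
0.001 for BA1, 0.0001 for BS1). The gene-specific engine further applies
REVEL cut-offs (PP3 > 0.7, BP4 < 0.4), functional assay grades (PS3/BS3),
same-residue comparison (PM5), multifactorial likelihood-ratio bins
(PP5/BP6), *BRCA1* domain location (PM1 in RING 1–101, COILED-COIL
1391–1424, BRCT 1650–1863; BP1 outside them when no splice effect < 0.2 is
predicted), and case-control enrichment (PS4 at OR ≥ 10). The generic engine
instead uses graded MetaRNN calibration bins and emulation toggles for
automated behaviours (BP3 on repeat-region missense, extended BP1, PM5 up to
strong, functional evidence hidden by default).

## Worked example

```r
library(varconcord)

v <- variant_record("VCV000055407", hgvs_c = "c.5408G>C",
                    hgvs_p = "p.Gly1803Ala", protein_position = 1803)
b <- annotation_bundle(allele_count = 0, allele_number = 90000,
                       revel = 0.552, metarnn = 0.62,
                       functional_result = "abnormal",
                       assay_strength = "strong")
classify_variant_canvig(v, b)
#> <canvig classification> LPV (+6 points)
#>   PM1 supporting (+1) [BRCT]
#>   PM2 supporting (+1) [absent]
#>   PS3 strong (+4)
classify_variant_auto(v, b)
#> <auto classification> VUS (+1 points)
#>   PM2 supporting (+1) [absent]
```

The variant is absent from controls (PM2), sits in the BRCT domain (PM1) and
has a strong abnormal functional assay (PS3), so the gene-specific engine
reaches LPV (+6). The generic engine does not see functional evidence by
default and its MetaRNN score is in the neutral band, so only PM2 fires and
the variant stays VUS — the typical source of discordance between the two
frameworks.

Cohort-level reports work from consolidated three-tier labels:

```r
counts <- reference_distribution_counts()
classification_distribution(rep(names(counts$varsome), counts$varsome))
#>   tier count percent
#> 1 P_LP    51    11.3
#> 2  VUS   111    24.7
#> 3 B_LB   288    64.0

ref <- reference_concordance()
a <- rep("VUS", ref[["n"]])
b <- c(rep("VUS", ref[["concordant"]]),
       rep("B_LB", ref[["n"]] - ref[["concordant"]]))
concordance_rate(build_confusion(a, b, labels = c("canvig", "varsome")))
#> Concordance: 58.9% (265/450), 95% CI 54.2-63.5%
```

A staged pipeline (`simulate`, `classify`, `compare`, `consensus`) ties the
pieces together with a JSON manifest per stage; see `?run_pipeline` or the
thin CLI at `inst/cli/varconcord.R`.

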