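---
title: "Methods: prioritizing novel secondary-findings variants in a population cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing novel secondary-findings variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgsf)
```

## The problem

Clinical sequencing guidelines recommend reporting medically actionable
("secondary" or "incidental") findings in a fixed panel of 59 genes
associated with highly penetrant, treatable conditions. In populations that
are underrepresented in the global reference databases — for example Middle
Eastern cohorts with elevated consanguinity — many potentially pathogenic
alleles in those genes are simply absent from dbSNP, gnomAD, TOPMed, the
1000 Genomes Project, ExAC, the GME Variome, HGMD and ClinVar. Finding them
requires working directly from cohort genotypes: screen every variant in the
panel's coding regions, keep the previously unrecorded ones with
computational evidence of deleteriousness, demand that they are rare but not
artifactual in the cohort itself, and then ask whether carriers look
clinically different from non-carriers.

`acmgsf` implements that workflow as a reusable, testable pipeline: a
prioritization cascade with an auditable funnel, frequency summaries by
subpopulation and disease category, an exact-test genotype–phenotype
association with a cardiovascular phenotype rubric, and segregation-based
selection of candidates for functional follow-up. Because the cohorts such
analyses run on are access-restricted, the package also ships a seeded
synthetic-cohort generator that reproduces the *decision structure* of the
analysis, so every stage can be verified end to end without any data
download.

## The prioritization cascade

Eight stages are applied to annotated, biallelic-split variant records.
Each stage is a pure predicate; the surviving set is the intersection of
all predicates, so permuting stages changes only the funnel counts, never
the outcome (this is a tested invariant).

| stage | predicate | default |
|---|---|---|
| `panel_region` | position inside a panel coding interval and gene in panel | 59-gene panel |
| `novelty` | absent from all eight databases | — |
| `cadd` | CADD phred ≥ threshold (inclusive) | 20 |
| `gerp` | GERP RS ≥ threshold (inclusive) | 3 |
| `frequency` | folded cohort MAF `min(AC, AN−AC)/AN` < threshold (strict) | 0.001 |
| `singleton` | cohort alt allele count AC ≥ 2 | — |
| `unrelated_carriers` | ≥ 2 carriers with pairwise kinship φ ≤ threshold | 0.0884 |
| `impact_effect` | impact MODERATE; intronic and loss-of-function effects removed | — |

Conventions worth spelling out:

* **Coordinates.** Half-open, 0-based intervals and positions internally
  (the BED convention); VCF and annotation files carry 1-based positions
  and are converted on ingest. Containment is strand-independent.
* **Thresholds.** The score thresholds are inclusive (`≥`) and the MAF
  bound strict (`<`), a literal reading of how such filters are usually
  stated. AN counts non-missing alleles only; a variant with AN = 0 is
  dropped with a warning.
* **"Unrelated".** The analysis this package generalizes never defines
  unrelatedness, so the default is the conventional third-degree kinship
  cut-off φ ≤ 0.0884 (KING threshold family), configurable via
  `cascade_params()`. The predicate asks for an independent set of size ≥ 2
  in the relatedness graph restricted to carriers; a size-2 independent set
  exists exactly when some carrier pair is non-adjacent, so the
  implementation does the exact O(k²) pairwise check rather than a general
  independent-set search. Carriers absent from the kinship table are
  treated as unrelated to everyone, with a warning.
* **Singletons.** AC ≥ 2 means a single *homozygous* carrier survives the
  singleton stage (and is then removed by the unrelated-carriers stage,
  which needs two distinct carriers). The funnel attributes the drop to the
  right stage either way.
* **Unknown consequence terms** are kept, with a warning — a new annotation
  vocabulary should fail loudly rather than silently empty the funnel.

The funnel reports, per stage, survivors, sequential drops, and the
marginal count of initial variants failing that predicate alone, so stage
attribution does not depend on stage order.

## Frequency summaries

`genotype_positive_frequency()` counts either alt alleles over `2n`
(default) or distinct carrier participants over `n`, per subpopulation and
per disease category. Both modes exist because published summaries of this
kind sometimes label allele-based numbers as participant frequencies; exact
inversion of the published table cells against the subpopulation sizes is
consistent with allele counting, hence the default. A participant carrying
two different surviving variants counts twice in allele numerators and once
in participant mode. Stored values are full precision; rounding (integer
percents for category distributions, one decimal for the cohort
genotype-positive rate) is presentation only.

## Phenotype rubric and association

A sample is **CVD-positive** iff its ECG is abnormal, or its ECG is
borderline *and* it has cardiovascular symptoms — chest pain or a
self-reported condition from a configurable term list (default: angina,
heart attack, heart failure, arrhythmia). Samples with missing ECG are not
classifiable and are excluded from both rows of the contingency table. The
comparator group is the genotype-negative cohort members with non-missing
phenotype.

The association test is Fisher's exact test, two-sided by the
point-probability convention: the p-value sums the hypergeometric
probabilities, over all tables with the observed margins, of tables whose
point probability does not exceed the observed one. The `≤` comparison uses
a relative tolerance of 1e-9 to make ties robust to floating-point noise.
Degenerate tables (a zero row or column margin) return p = 1 by convention.
The implementation (a `dhyper()` sum) is cross-checked in the test suite
against an independent `choose()`-based enumeration for *every* 2×2 table
up to total count 40, and against `stats::fisher.test()` on random tables.

Odds ratios are the cross-product `(ad)/(bc)`; the Haldane–Anscombe
correction (add 0.5 to every cell) is applied automatically iff the table
has a zero cell, and that choice is recorded in the result. No
multiple-testing correction is applied, matching the workflow the package
implements; the candidate sets involved are a handful of variants.

## Candidate selection

`select_candidates()` applies the segregation criteria: CVD-rubric
association p < α (default 0.05), at least `min_cvd_carriers` (default 2)
CVD-positive carriers, and at least `min_parental_history_carriers`
(default 2) carriers reporting parental heart disease. Two deliberate
readings where the source workflow is loose:

* Significance applies to the CVD-rubric association only. Parental
  history is supporting evidence — a variant whose parental-history
  association is itself non-significant can still be selected, which
  matches how such candidates are reported in practice.
* "Carriers should have positive parental history" names no count; the
  default threshold is ≥ 2 carriers and is configuration-exposed.

The output ledger records every criterion's value and pass/fail flag per
variant, so near-misses are auditable, and the selection flag is tested to
equal the conjunction of the per-criterion flags. Selection is monotone in
evidence (lower p, more supporting carriers can never de-select; a tested
property). Carriers of known pathogenic variants in cardiovascular-category
genes can be excluded from association and selection via a supplied variant
list.

## The synthetic cohort generator

`simulate_cohort()` emits the exact file formats the readers consume (VCF
4.2 plus four TSVs) together with a truth table assigning each planted
variant one of nine *fates*: eight `fails_*` fates, one per cascade stage,
and `survives_all`. Each planted variant is constructed to fail exactly its
fated predicate and satisfy all others, with one necessary exception: a
`fails_singleton` variant has a single carrier and therefore also lacks two
unrelated carriers, so fates are defined as the *first failing predicate in
canonical stage order*. By construction the funnel then drops exactly the
planted count at each stage, and the surviving set equals the
`survives_all` keys — which the tests re-verify with an independent
brute-force predicate oracle, not the cascade code.

Default study conditions:

* **Cohort.** n = 600 samples (a 10× scale-down of the 6045-participant
  study the pipeline emulates) drawn from six subpopulations with weights
  proportional to the published sizes (ADM 1180, AFR 92, GAR 2311, PAR
  1052, WEP 1372, SAS 38). 40 multi-member families of size 2–3 with
  within-family kinship φ ∈ {0.25, 0.125}; everyone else unrelated.
* **MAF threshold scaling.** At n = 600 the analysis threshold 0.001 is
  unsatisfiable for any variant that also clears the singleton filter
  (AC ≥ 2 implies MAF ≥ 2/1200). The generator therefore carries its own
  planting threshold, default 0.01 — the analysis threshold scaled by the
  same 10× factor as the cohort — and refuses infeasible combinations with
  an explicit error rather than adjusting silently. The cascade must be run
  with the bundle's threshold (`cascade_params(maf_threshold = ...)`); its
  own default remains the analysis value 0.001.
* **Carriers.** Heterozygous carriers drawn from distinct family units
  (guaranteeing the unrelated-carrier predicate by construction): 4 per
  variant by default; 1 for `fails_singleton`; 2 related ones for
  `fails_unrelated`; `ceiling(threshold · 2n)` for `fails_maf`. Genotype
  missingness (default 1%) is placed on non-carrier cells only, so planted
  allele counts are exact.
* **Phenotypes.** A logistic-odds model: carriers of planted high-effect
  survivors have their odds of CVD-positivity (and of parental history)
  multiplied by a configured odds ratio; positives are realized as
  abnormal ECG (70%) or borderline ECG with a symptom, negatives as normal
  or symptom-free borderline ECG, so the rubric recovers the latent status
  exactly wherever the ECG is not missing (2% by default). Background
  prevalences (CVD 0.08, borderline 0.10, chest pain 0.08, parental
  history 0.15) are free parameters chosen as plausible middle-aged
  population values; the real biobank prevalences are not published.
* **Effect sizes.** The published anchor for a convincing candidate is an
  odds ratio near 6.6, and that value is used in the calibration studies
  below. The *demo* bundle's default `carrier_or` is `Inf` — the
  documented deterministic limit in which every carrier is positive —
  because the demo's planted positives are meant to be recovered with
  sensitivity 1.0 at any seed, which no finite odds ratio can guarantee at
  the carrier counts a rare variant allows. Three of the six planted
  survivors carry the effect; the other three are phenotype-null.
* **Determinism.** One global seed, split into independent per-surface
  sub-seeds (samples/kinship, genotypes, phenotypes), so a surface can be
  regenerated alone. The same configuration yields byte-identical files; a
  tested contract.

What the generator does *not* model: linkage disequilibrium, realistic
site-frequency spectra, admixture, genotyping error, or any correlation
between annotation scores and allele frequency. Passing tests therefore
demonstrate that the *decision logic* is correct on data satisfying the
stated assumptions — not that the pipeline is robust to the failure modes
of real sequencing data (batch effects, annotation errors, cryptic
relatedness beyond the supplied kinship table).

## Calibration and numerical checks

The test suite and `scripts/acceptance.R` recompute, at fixed problem
sizes chosen to keep a full run in tens of seconds:

* **Cascade vs oracle.** 100 random bundles (150–250 samples, 18–54
  planted variants each): cascade survivors equal the brute-force oracle's,
  funnels are monotone, and the surviving set is invariant under random
  stage permutations.
* **Exact test.** Exhaustive agreement with enumeration for all 2×2 tables
  with N ≤ 40 (≈ 136k tables), to < 1e-12.
* **Type-I error.** 1000 null cohorts (n = 600, 10 carriers, OR = 1): the
  rejection rate at α = 0.05 stays at or below nominal within two binomial
  standard errors — the exact test is conservative on discrete tables, and
  the observed rate is typically near 0.02–0.03. For the same reason null
  p-values are *not* uniform (they are stochastically larger than
  uniform), so calibration is asserted as conservatism at several α
  levels rather than as a distributional uniformity test.
* **Effect recovery.** 200 cohorts of n = 2000 with 40 carriers at planted
  OR 6.6: the mean log-OR lands within three Monte-Carlo standard errors
  of log 6.6, and the median estimate inside the pre-computed [5.0, 8.6]
  recovery band. The estimator inherits a small negative bias from the
  occasional Haldane correction; at these problem sizes it is well inside
  the Monte-Carlo band the test enforces.
* **Selector.** Candidate profiles shaped like the two published
  cardiovascular candidates (p = 0.0290 with 4/11 affected carriers;
  p = 0.0364 with 5/9) are selected, and `run_all()` on the default demo
  bundle recovers every planted high-effect survivor (sensitivity 1.0).

## Known limitations

* The shipped gene→category mapping is reconstructed from the
  secondary-findings v2.0 phenotype groupings; a handful of multi-system
  genes (e.g. *GLA*) are judgement calls, and the mapping is data
  (editable YAML), not code.
* The shipped coding intervals are synthetic placeholders (the BED is
  named accordingly); supply a real transcript-model BED for real data.
  No transcript-model computation, liftover, or left-alignment is
  performed; CADD, GERP and consequence annotations are consumed, never
  computed.
* Database membership is boolean — there is no ClinVar assertion-level
  logic.
* Published odds ratios from the emulated analysis (6.619, 4.138, 4.755)
  are not reconstructible without the unpublished background phenotype
  counts; they serve as effect-size anchors for the simulator, not as
  reproduction targets.
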