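Package: acmgsf
Title: Prioritization of Novel ACMG Secondary-Findings Variants in Population Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for nominating novel, potentially pathogenic
    variants in the ACMG secondary-findings gene panel from cohort sequencing
    data. Implements an eight-stage prioritization cascade (panel coding
    regions, absence from eight population and disease databases, CADD and
    GERP deleteriousness thresholds, cohort minor allele frequency, singleton
    removal, kinship-aware unrelated-carrier support, and consequence
    impact/effect rules) with a per-stage funnel report; subpopulation and
    disease-category frequency summaries; a cardiovascular phenotype rubric
    with two-sided Fisher exact genotype-phenotype association and
    Haldane-corrected odds ratios; segregation criteria for selecting
    candidates for functional follow-up; and a seeded synthetic-cohort
    generator that emulates the decision structure of the analysis so every
    stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    vcfR,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
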