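test_that("allele frequencies reproduce the published subpopulation cells", {
  # WEP: 90 alt alleles over 2 x 1372 participants; PAR: 17 over 2 x 1052
  expect_equal(round(allele_frequency(90, 2744), 8), 0.03279883)
  expect_equal(round(allele_frequency(17, 2104), 9), 0.008079848)
  expect_equal(allele_frequency(0, 184), 0)
  expect_error(allele_frequency(1, 0), "an must be positive")
  expect_error(allele_frequency(5, 4), "0 <= ac <= an")
})

test_that("category distribution reproduces the published percentages", {
  panel <- acmg_panel()
  # 74 surviving variants: 21 cardiovascular in 10 genes, 17 malignant
  # hyperthermia in 2 genes, the rest spread over the other categories
  cardio_genes <- rep(c("DSP", "LMNA", "SCN5A", "MYBPC3", "TPM1", "RYR2",
                        "MYH7", "TNNT2", "KCNQ1", "PKP2"),
                      c(3, 2, 2, 2, 2, 2, 2, 2, 2, 2))
  mh_genes <- rep(c("RYR1", "CACNA1S"), c(9, 8))
  other_genes <- c(rep("BRCA2", 14), rep("LDLR", 8),
                   rep(c("ATP7B", "GLA"), c(7, 7)))
  genes <- c(cardio_genes, mh_genes, other_genes)
  v <- do.call(rbind, lapply(seq_along(genes), function(i) {
    make_variant(sprintf("1:%d:A:G", i), gene = genes[i])
  }))
  expect_equal(nrow(v), 74)
  dist <- category_distribution(v, panel)
  cardio <- dist[dist$category == "cardiovascular", ]
  mh <- dist[dist$category == "malignant_hyperthermia", ]
  expect_equal(cardio$n_variants, 21)
  expect_equal(cardio$n_genes, 10)
  expect_equal(cardio$percent, 28)
  expect_equal(mh$n_variants, 17)
  expect_equal(mh$n_genes, 2)
  expect_equal(mh$percent, 23)
  expect_equal(sum(dist$n_variants), 74)
  expect_equal(sum(dist$fraction), 1)
  # single-category input -> 100%
  one <- category_distribution(make_variant("1:1:A:G", gene = "DSP"), panel)
  expect_equal(one$percent[one$category == "cardiovascular"], 100)
  # rounded percents sum to 100 up to rounding slack
  withr::with_seed(3, {
    genes <- sample(panel$genes$gene, 50, replace = TRUE)
    v <- do.call(rbind, lapply(seq_along(genes), function(i) {
      make_variant(sprintf("1:%d:A:G", i), gene = genes[i])
    }))
    d <- category_distribution(v, panel)
    expect_lte(abs(sum(d$percent) - 100), length(unique(genes)))
  })
})

test_that("subpopulation frequencies count alleles or participants as asked", {
  panel <- acmg_panel()
  samples <- tibble::tibble(
    sample_id = c("A1", "A2", "G1", "G2", "G3"),
    subpopulation = c("AFR", "AFR", "GAR", "GAR", "GAR"))
  geno <- make_geno(samples$sample_id, list(
    `6:1:A:G` = c(2L, 0L, 1L, 0L, 0L),    # DSP: hom AFR + het GAR
    `19:2:A:G` = c(0L, 0L, 1L, 0L, 0L)))  # LDLR: same GAR carrier
  v <- rbind(make_variant("6:1:A:G", gene = "DSP"),
             make_variant("19:2:A:G", gene = "LDLR"))
  fa <- genotype_positive_frequency(v, geno, samples, panel, "allele")
  afr_all <- fa[fa$category == "all" & fa$subpopulation == "AFR", ]
  expect_equal(afr_all$numerator, 2)       # one homozygote
  expect_equal(afr_all$denominator, 4)
  gar_all <- fa[fa$category == "all" & fa$subpopulation == "GAR", ]
  expect_equal(gar_all$numerator, 2)       # two alleles across two variants
  fp <- genotype_positive_frequency(v, geno, samples, panel, "participant")
  gar_p <- fp[fp$category == "all" & fp$subpopulation == "GAR", ]
  expect_equal(gar_p$numerator, 1)         # same participant counts once
  expect_equal(gar_p$frequency, 1 / 3)
  # empty subpopulation reports 0 with its zero denominator
  sas <- fa[fa$category == "all" & fa$subpopulation == "SAS", ]
  expect_equal(sas$frequency, 0)
  expect_equal(sas$denominator, 0)
  # per-category restriction: the LDLR allele only counts under FH
  gar_fh <- fa[fa$category == "familial_hypercholesteremia" &
                 fa$subpopulation == "GAR", ]
  expect_equal(gar_fh$numerator, 1)
})

test_that("frequency summaries agree with a brute-force recount and add up", {
  panel <- acmg_panel()
  cfg <- small_config(71)
  sim <- simulate_cohort(cfg)
  surv <- sim$variants[sim$variants$key %in%
                         sim$truth$key[sim$truth$fate == "survives_all"], ]
  fa <- genotype_positive_frequency(surv, sim$genotypes, sim$samples, panel)
  cat_of_gene <- setNames(panel$genes$category, panel$genes$gene)
  for (r in which(fa$subpopulation != "all" & fa$category != "all")) {
    ids <- sim$samples$sample_id[sim$samples$subpopulation ==
                                   fa$subpopulation[r]]
    keys <- surv$key[cat_of_gene[surv$gene] == fa$category[r]]
    manual <- sum(sim$genotypes[ids, keys, drop = FALSE], na.rm = TRUE)
    expect_equal(fa$numerator[r], manual)
  }
  # additivity across subpopulations and categories
  all_all <- fa$numerator[fa$subpopulation == "all" & fa$category == "all"]
  expect_equal(sum(fa$numerator[fa$subpopulation != "all" &
                                  fa$category == "all"]), all_all)
  expect_equal(sum(fa$numerator[fa$subpopulation == "all" &
                                  fa$category != "all"]), all_all)
})

test_that("genotype-positive rate matches the published cohort share", {
  expect_equal(round(genotype_positive_rate(270, 6045), 1), 4.5)
  expect_equal(genotype_positive_rate(0, 6045), 0)
  expect_equal(genotype_positive_rate(6045, 6045), 100)
  expect_error(genotype_positive_rate(1, 0), "positive")
})
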