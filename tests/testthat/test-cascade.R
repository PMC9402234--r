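test_that("novelty requires absence from all eight databases", {
  v <- rbind(make_variant("1:1:A:G", flags = FALSE),
             make_variant("1:2:A:G",
                          flags = c(rep(FALSE, 6), TRUE, FALSE)), # hgmd only
             make_variant("1:3:A:G", flags = TRUE))
  expect_equal(filter_novel(v)$key, "1:1:A:G")
  v_na <- make_variant("1:4:A:G")
  v_na$hgmd <- NA
  expect_error(filter_novel(v_na), "unpopulated membership flag")
  # random flag tables agree with the plain conjunction oracle
  withr::with_seed(1, {
    flags <- matrix(runif(50 * 8) < 0.3, ncol = 8)
    v <- do.call(rbind, lapply(1:50, function(i) {
      make_variant(sprintf("1:%d:A:G", i), flags = flags[i, ])
    }))
    expect_setequal(filter_novel(v)$key, v$key[rowSums(flags) == 0])
  })
})

test_that("deleteriousness thresholds are inclusive", {
  v <- rbind(
    make_variant("6:1:A:G", cadd = 24.5, gerp = 5.79),  # DSP-like scores
    make_variant("1:2:A:G", cadd = 25.9, gerp = 4.9),   # LMNA-like scores
    make_variant("1:3:A:G", cadd = 20.0, gerp = 3.0),   # on the boundary
    make_variant("1:4:A:G", cadd = 19.99, gerp = 5.0),
    make_variant("1:5:A:G", cadd = 30.0, gerp = 2.99))
  expect_setequal(filter_deleterious(v)$key,
                  c("6:1:A:G", "1:2:A:G", "1:3:A:G"))
  v$cadd[1] <- NA
  expect_error(filter_deleterious(v), "missing CADD/GERP")
})

test_that("MAF filter folds the allele frequency over non-missing alleles", {
  ids <- sprintf("S%04d", 1:6000)
  geno <- make_geno(ids, list(
    `1:1:A:G` = rep(c(1L, 0L), c(2, 5998)),    # AC 2 / AN 12000 = 1.67e-4
    `1:2:A:G` = rep(c(1L, 0L), c(13, 5987)),   # AC 13 / AN 12000 = 1.08e-3
    `1:3:A:G` = rep(0L, 6000)))                # AC 0
  v <- rbind(make_variant("1:1:A:G"), make_variant("1:2:A:G"),
             make_variant("1:3:A:G"))
  kept <- filter_frequency(v, geno, maf_threshold = 0.001)
  expect_setequal(kept$key, c("1:1:A:G", "1:3:A:G"))
  # folding: a near-fixed alt allele is "rare" on the folded scale
  geno2 <- make_geno(ids, list(`1:9:A:G` = rep(c(2L, 1L), c(5999, 1))))
  kept2 <- filter_frequency(make_variant("1:9:A:G"), geno2,
                            maf_threshold = 0.001)
  expect_equal(kept2$key, "1:9:A:G")
  # AN = 0 drops the variant with a warning
  geno3 <- make_geno(ids[1:3], list(`1:8:A:G` = rep(NA_integer_, 3)))
  expect_warning(
    kept3 <- filter_frequency(make_variant("1:8:A:G"), geno3, 0.001),
    "AN = 0")
  expect_equal(nrow(kept3), 0)
})

test_that("singleton removal keeps AC >= 2 including single homozygotes", {
  ids <- c("A", "B", "C")
  geno <- make_geno(ids, list(
    `1:1:A:G` = c(1L, 0L, 0L),   # lone heterozygote: dropped
    `1:2:A:G` = c(2L, 0L, 0L),   # single homozygote, AC 2: kept
    `1:3:A:G` = c(1L, 1L, 0L)))  # two heterozygotes: kept
  v <- rbind(make_variant("1:1:A:G"), make_variant("1:2:A:G"),
             make_variant("1:3:A:G"))
  expect_setequal(filter_singletons(v, geno)$key,
                  c("1:2:A:G", "1:3:A:G"))
})

test_that("unrelated-carrier support needs a non-adjacent carrier pair", {
  ids <- c("A", "B", "C", "D")
  kin <- make_kinship(c("A", "C"), c("B", "D"), c(0.25, 0.125))
  geno <- make_geno(ids, list(
    `1:1:A:G` = c(1L, 1L, 0L, 0L),   # only related carriers A-B
    `1:2:A:G` = c(1L, 1L, 1L, 0L),   # A-B related, but {A,C} unrelated
    `1:3:A:G` = c(1L, 0L, 0L, 0L),   # one carrier
    `1:4:A:G` = c(0L, 0L, 1L, 1L)))  # C-D at phi 0.125
  v <- do.call(rbind, lapply(sprintf("1:%d:A:G", 1:4), make_variant))
  kept <- filter_unrelated_carriers(v, geno, kin, phi_threshold = 0.0884)
  expect_setequal(kept$key, "1:2:A:G")
  # second-degree pairs pass under a first-degree-only threshold
  kept2 <- filter_unrelated_carriers(v, geno, kin, phi_threshold = 0.2)
  expect_setequal(kept2$key, c("1:2:A:G", "1:4:A:G"))
  # carriers outside the graph are unrelated to everyone, with a warning
  geno5 <- make_geno(c("X", "Y"), list(`1:5:A:G` = c(1L, 1L)))
  expect_warning(
    kept3 <- filter_unrelated_carriers(make_variant("1:5:A:G"), geno5, kin),
    "absent from the kinship graph")
  expect_equal(kept3$key, "1:5:A:G")
})

test_that("impact/effect keeps moderate missense, drops intronic and LoF", {
  v <- rbind(
    make_variant("1:1:A:G", effect = "missense_variant", impact = "MODERATE"),
    make_variant("1:2:A:G", effect = "stop_gained", impact = "HIGH"),
    make_variant("1:3:A:G", effect = "intron_variant", impact = "MODIFIER"),
    make_variant("1:4:A:G", effect = "frameshift_variant", impact = "HIGH"),
    make_variant("1:5:A:G", effect = "synonymous_variant", impact = "LOW"))
  expect_equal(filter_impact_effect(v)$key, "1:1:A:G")
  v6 <- make_variant("1:6:A:G", effect = "made_up_term", impact = "MODERATE")
  expect_warning(kept <- filter_impact_effect(v6), "unknown effect term")
  expect_equal(kept$key, "1:6:A:G")
})

test_that("the funnel drops each planted fate at its own stage", {
  panel <- acmg_panel()
  cfg <- small_config(55)
  sim <- simulate_cohort(cfg)
  funnel <- suppressWarnings(
    run_cascade(sim$variants, sim$genotypes, sim$kinship, panel,
                cascade_params(maf_threshold = cfg$maf_threshold)))
  stage_fate <- c(panel_region = "fails_panel", novelty = "fails_novelty",
                  cadd = "fails_cadd", gerp = "fails_gerp",
                  frequency = "fails_maf", singleton = "fails_singleton",
                  unrelated_carriers = "fails_unrelated",
                  impact_effect = "fails_impact_effect")
  planted <- table(sim$truth$fate)
  for (st in names(stage_fate)) {
    expect_equal(funnel$n_dropped[funnel$stage == st],
                 unname(planted[[stage_fate[[st]]]]), label = st)
  }
  expect_setequal(surviving_variants(funnel)$key,
                  sim$truth$key[sim$truth$fate == "survives_all"])
  expect_true(all(diff(funnel$n_surviving) <= 0))
})

test_that("degenerate inputs give sane funnels", {
  panel <- acmg_panel()
  sim <- simulate_cohort(small_config(56))
  empty <- sim$variants[0, ]
  funnel <- run_cascade(empty, sim$genotypes, sim$kinship, panel,
                        cascade_params(maf_threshold = 0.02))
  expect_true(all(funnel$n_surviving == 0))
  expect_equal(attr(funnel, "initial"), 0)
  # all-pass bundle: survivors only -> flat funnel
  surv <- sim$variants[sim$variants$key %in%
                         sim$truth$key[sim$truth$fate == "survives_all"], ]
  flat <- suppressWarnings(
    run_cascade(surv, sim$genotypes, sim$kinship, panel,
                cascade_params(maf_threshold = 0.02)))
  expect_true(all(flat$n_surviving == nrow(surv)))
  expect_true(all(flat$n_dropped == 0))
})

test_that("the surviving set is invariant to stage order", {
  panel <- acmg_panel()
  cfg <- small_config(57)
  sim <- simulate_cohort(cfg)
  params <- cascade_params(maf_threshold = cfg$maf_threshold)
  base <- suppressWarnings(
    run_cascade(sim$variants, sim$genotypes, sim$kinship, panel, params))
  withr::with_seed(58, {
    for (i in 1:5) {
      perm <- sample(base$stage)
      alt <- suppressWarnings(
        run_cascade(sim$variants, sim$genotypes, sim$kinship, panel, params,
                    stage_order = perm))
      expect_setequal(surviving_variants(alt)$key,
                      surviving_variants(base)$key)
    }
  })
})
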