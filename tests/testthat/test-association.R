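test_that("the cardiovascular rubric classifies ECG/symptom combinations", {
  ph <- rbind(
    make_pheno("a", ecg = "abnormal"),
    make_pheno("b", ecg = "borderline", chest_pain = TRUE),
    make_pheno("c", ecg = "borderline", conditions = "angina"),
    make_pheno("d", ecg = "borderline"),
    make_pheno("e", ecg = "normal", chest_pain = TRUE),
    make_pheno("f", ecg = "missing", chest_pain = TRUE),
    make_pheno("g", ecg = "borderline", conditions = "Heart Failure;other"))
  expect_equal(classify_cvd_phenotype(ph),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, NA, TRUE))
  # unknown condition terms do not count as cardiovascular
  ph2 <- make_pheno("h", ecg = "borderline", conditions = "hay fever")
  expect_false(classify_cvd_phenotype(ph2))
})

test_that("contingency tables split carriers by phenotype and drop missing", {
  ids <- sprintf("S%02d", 1:30)
  geno <- make_geno(ids, list(`6:1:A:G` = rep(c(1L, 0L), c(11, 19))))
  # 11 carriers: 3 abnormal ECG, 1 borderline with chest pain, 7 negative
  ph <- rbind(
    make_pheno(ids[1:3], ecg = "abnormal"),
    make_pheno(ids[4], ecg = "borderline", chest_pain = TRUE),
    make_pheno(ids[5:11]),
    make_pheno(ids[12:13], ecg = "abnormal"),
    make_pheno(ids[14:30]))
  tab <- build_contingency("6:1:A:G", geno, ph, "cvd_rubric")
  expect_equal(unname(tab["carrier", ]), c(4, 7))
  expect_equal(unname(tab["non_carrier", ]), c(2, 17))
  # parental-history columns: 6 of 9 carriers report it
  geno2 <- make_geno(ids, list(`1:2:T:G` = rep(c(1L, 0L), c(9, 21))))
  ph2 <- rbind(make_pheno(ids[1:6], parental = TRUE),
               make_pheno(ids[7:30]))
  tab2 <- build_contingency("1:2:T:G", geno2, ph2, "parental_history")
  expect_equal(unname(tab2["carrier", ]), c(6, 3))
  # samples with missing ECG leave both rows
  ph3 <- ph
  ph3$ecg[c(1, 20)] <- "missing"
  tab3 <- build_contingency("6:1:A:G", geno, ph3, "cvd_rubric")
  expect_equal(sum(tab3), 28)
  # zero carriers -> undefined association
  geno3 <- make_geno(ids, list(`1:3:A:C` = rep(0L, 30)))
  expect_error(build_contingency("1:3:A:C", geno3, ph), "no carriers")
})

test_that("two-sided Fisher p matches hand enumeration on known tables", {
  expect_equal(fisher_exact_two_sided(c(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_two_sided(c(3, 1, 1, 3)), 34 / 70)
  expect_equal(fisher_exact_two_sided(c(5, 0, 0, 5)), 2 / 252)
  # degenerate margins return 1 by convention
  expect_equal(fisher_exact_two_sided(c(0, 0, 3, 4)), 1)
  expect_equal(fisher_exact_two_sided(c(0, 4, 0, 6)), 1)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  withr::with_seed(17, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, lambda = sample(c(2, 5, 12), 1)), 2)
      expect_equal(fisher_exact_two_sided(tab),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  withr::with_seed(23, {
    for (i in 1:50) {
      t0 <- matrix(rpois(4, 6), 2)
      t1 <- t0[2:1, 2:1]
      expect_equal(fisher_exact_two_sided(t0), fisher_exact_two_sided(t1))
    }
  })
})

test_that("strengthening a positive diagonal never increases the p-value", {
  withr::with_seed(29, {
    tried <- 0
    for (i in 1:200) {
      t0 <- matrix(rpois(4, 5), 2)
      a <- t0[1, 1]; b <- t0[1, 2]; c <- t0[2, 1]; d <- t0[2, 2]
      if (b < 1 || c < 1 || a * d < b * c) next
      tried <- tried + 1
      p0 <- fisher_exact_two_sided(c(a, b, c, d))
      p1 <- fisher_exact_two_sided(c(a + 1, b - 1, c - 1, d + 1))
      expect_lte(p1, p0 + 1e-12)
    }
    expect_gt(tried, 20)
  })
})

test_that("odds ratios follow the cross-product with optional correction", {
  expect_equal(odds_ratio(c(6, 3, 20, 60)), 6)
  expect_equal(odds_ratio(c(1, 1, 1, 1)), 1)
  expect_equal(odds_ratio(c(2, 0, 5, 5), correction = "haldane"), 5)
  # transposition invariance
  t0 <- matrix(c(7, 3, 2, 9), 2)
  expect_equal(odds_ratio(t0), odds_ratio(t(t0)))
  # scaling a row leaves the uncorrected OR unchanged
  expect_equal(odds_ratio(c(7, 3, 2, 9)), odds_ratio(c(21, 9, 2, 9)))
})

test_that("associate_variant records the automatic Haldane correction", {
  ids <- sprintf("S%02d", 1:20)
  geno <- make_geno(ids, list(`1:1:A:G` = rep(c(1L, 0L), c(4, 16))))
  ph <- rbind(make_pheno(ids[1:4], ecg = "abnormal"),
              make_pheno(ids[5:20]))
  res <- associate_variant("1:1:A:G", geno, ph)
  expect_true(res$haldane) # zero cell: no carrier-negatives
  expect_equal(res$odds_ratio,
               odds_ratio(res$table, correction = "haldane"))
  expect_equal(res$n_carriers, 4L)
  expect_equal(res$n_carrier_positive, 4L)
  expect_lt(res$p_two_sided, 0.05)
})
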