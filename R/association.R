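# Genotype-phenotype association: the cardiovascular phenotype rubric, 2x2
# contingency construction, a two-sided Fisher exact test (point-probability
# convention) and odds ratios with optional Haldane-Anscombe correction.

#' Default self-reported cardiovascular condition terms
#'
#' Terms counted as a self-reported cardiovascular condition by the
#' phenotype rubric. Matching is case-insensitive on whole semicolon-
#' separated entries.
#' @export
cvd_condition_terms <- function() {
  c("angina", "heart attack", "heart failure", "arrhythmia")
}

#' Cardiovascular phenotype rubric
#'
#' A sample is CVD-positive iff its ECG is abnormal, or its ECG is
#' borderline and it has cardiovascular symptoms (chest pain or a
#' self-reported condition from `condition_terms`). Samples with missing ECG
#' are not classifiable and return `NA`.
#'
#' @param phenotypes tibble of phenotype records ([read_phenotypes()]).
#' @param condition_terms terms counted as self-reported conditions.
#' @return logical vector (`NA` where ECG is missing).
#' @export
classify_cvd_phenotype <- function(phenotypes,
                                   condition_terms = cvd_condition_terms()) {
  has_condition <- vapply(phenotypes$self_reported_conditions, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    any(tolower(trimws(strsplit(s, ";", fixed = TRUE)[[1]])) %in%
          tolower(condition_terms))
  }, logical(1), USE.NAMES = FALSE)
  symptoms <- phenotypes$chest_pain | has_condition
  out <- phenotypes$ecg == "abnormal" |
    (phenotypes$ecg == "borderline" & symptoms)
  out[phenotypes$ecg == "missing"] <- NA
  out
}

#' Build a 2x2 carrier-by-phenotype contingency table
#'
#' Rows are carrier status (dosage >= 1) and columns phenotype-positive /
#' negative under the chosen definition: the cardiovascular rubric or
#' parental heart-disease history. Samples with a missing phenotype are
#' excluded from both rows; the comparator group is the genotype-negative
#' cohort members with non-missing phenotype.
#'
#' @param variant_key variant key (a column of `genotypes`).
#' @param genotypes dosage matrix.
#' @param phenotypes tibble of phenotype records.
#' @param column_def `"cvd_rubric"` or `"parental_history"`.
#' @param condition_terms see [classify_cvd_phenotype()].
#' @return a `contingency_table`: 2x2 integer matrix, rows carrier /
#'   non_carrier, columns positive / negative.
#' @export
build_contingency <- function(variant_key, genotypes, phenotypes,
                              column_def = c("cvd_rubric",
                                             "parental_history"),
                              condition_terms = cvd_condition_terms()) {
  column_def <- match.arg(column_def)
  if (!variant_key %in% colnames(genotypes)) {
    stop("build_contingency: variant '", variant_key,
         "' not in genotype matrix", call. = FALSE)
  }
  i <- match(rownames(genotypes), phenotypes$sample_id)
  if (anyNA(i)) {
    stop("build_contingency: phenotype record(s) missing for sample(s): ",
         paste(head(rownames(genotypes)[is.na(i)], 5), collapse = ", "),
         call. = FALSE)
  }
  ph <- phenotypes[i, ]
  positive <- switch(column_def,
                     cvd_rubric = classify_cvd_phenotype(ph, condition_terms),
                     parental_history = ph$parental_heart_disease)
  dos <- genotypes[, variant_key]
  carrier <- !is.na(dos) & dos >= 1
  ok <- !is.na(positive)
  if (!any(carrier[ok])) {
    stop("build_contingency: variant '", variant_key,
         "' has no carriers with phenotype data; association undefined",
         call. = FALSE)
  }
  tab <- matrix(c(sum(carrier & ok & positive),
                  sum(carrier & ok & !positive),
                  sum(!carrier & ok & positive),
                  sum(!carrier & ok & !positive)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("carrier", "non_carrier"),
                                c("positive", "negative")))
  structure(tab, class = c("contingency_table", "matrix", "array"))
}

as_table2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(dim(table) == c(2, 2))
    tab <- table
  } else {
    stopifnot(length(table) == 4)
    tab <- matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  }
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("contingency table cells must be finite and non-negative",
         call. = FALSE)
  }
  tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities, over all tables with the observed
#' margins, of the tables whose point probability does not exceed that of
#' the observed table (point-probability two-sided convention; the
#' comparison uses a relative tolerance of 1e-9). Degenerate tables with a
#' zero row or column margin return p = 1 by convention.
#'
#' @param table 2x2 matrix (rows carrier status, columns phenotype) or a
#'   length-4 vector `(a, b, c, d)` in row-major order.
#' @return the two-sided p-value, in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(c(3, 1, 1, 3)) # 34/70
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as_table2x2(table)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c        # positive-column margin
  nn <- b + d       # negative-column margin
  k <- a + b        # carrier-row margin
  if (m == 0 || nn == 0 || k == 0 || c + d == 0) {
    return(1.0)
  }
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-9)])
  min(1, p)
}

#' Odds ratio of a 2x2 table
#'
#' The cross-product ratio `(a d) / (b c)`; with the Haldane-Anscombe
#' correction, 0.5 is added to every cell first (stabilizing tables with
#' zero cells).
#'
#' @inheritParams fisher_exact_two_sided
#' @param correction `"none"` or `"haldane"`.
#' @return positive real (possibly `Inf`/`NaN` without correction when a
#'   denominator cell is zero).
#' @examples
#' odds_ratio(c(6, 3, 20, 60)) # 6
#' odds_ratio(c(2, 0, 5, 5), correction = "haldane") # 5
#' @export
odds_ratio <- function(table, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  tab <- as_table2x2(table)
  if (correction == "haldane") tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Associate one variant with a phenotype definition
#'
#' Composes [build_contingency()], [fisher_exact_two_sided()] and
#' [odds_ratio()]. The Haldane-Anscombe correction is applied automatically
#' iff the table contains a zero cell, and the choice is recorded in the
#' result.
#'
#' @inheritParams build_contingency
#' @return an `association_result`: list with `key`, `column_def`, `table`,
#'   `p_two_sided`, `odds_ratio`, `haldane` (logical), `n_carriers`,
#'   `n_carrier_positive`.
#' @export
associate_variant <- function(variant_key, genotypes, phenotypes,
                              column_def = c("cvd_rubric",
                                             "parental_history"),
                              condition_terms = cvd_condition_terms()) {
  column_def <- match.arg(column_def)
  tab <- build_contingency(variant_key, genotypes, phenotypes, column_def,
                           condition_terms)
  haldane <- any(tab == 0)
  structure(list(
    key = variant_key,
    column_def = column_def,
    table = tab,
    p_two_sided = fisher_exact_two_sided(tab),
    odds_ratio = odds_ratio(tab, if (haldane) "haldane" else "none"),
    haldane = haldane,
    n_carriers = as.integer(sum(tab[1, ])),
    n_carrier_positive = as.integer(tab[1, 1])),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> ", x$key, " [", x$column_def, "]\n",
      "  carriers ", x$n_carriers, " (", x$n_carrier_positive,
      " positive); P = ", signif(x$p_two_sided, 4), ", OR = ",
      signif(x$odds_ratio, 4),
      if (x$haldane) " (Haldane-corrected)" else "", "\n", sep = "")
  invisible(x)
}

#' Associate every variant in a set under one phenotype definition
#'
#' Variants without phenotyped carriers are skipped with a warning (their
#' association is undefined).
#'
#' @param variant_keys character vector of variant keys.
#' @inheritParams build_contingency
#' @return tibble with one row per associated variant: `key`, `column_def`,
#'   `a`, `b`, `c`, `d`, `p_two_sided`, `odds_ratio`, `haldane`,
#'   `n_carriers`, `n_carrier_positive`.
#' @export
associate_variants <- function(variant_keys, genotypes, phenotypes,
                               column_def = c("cvd_rubric",
                                              "parental_history"),
                               condition_terms = cvd_condition_terms()) {
  column_def <- match.arg(column_def)
  rows <- list()
  skipped <- character(0)
  for (k in variant_keys) {
    res <- tryCatch(
      associate_variant(k, genotypes, phenotypes, column_def,
                        condition_terms),
      error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, k)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      key = res$key, column_def = res$column_def,
      a = res$table[1, 1], b = res$table[1, 2],
      c = res$table[2, 1], d = res$table[2, 2],
      p_two_sided = res$p_two_sided, odds_ratio = res$odds_ratio,
      haldane = res$haldane, n_carriers = res$n_carriers,
      n_carrier_positive = res$n_carrier_positive)
  }
  if (length(skipped) > 0) {
    warning("associate_variants: skipped ", length(skipped),
            " variant(s) without phenotyped carriers", call. = FALSE)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(key = character(), column_def = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p_two_sided = double(),
                          odds_ratio = double(), haldane = logical(),
                          n_carriers = integer(),
                          n_carrier_positive = integer()))
  }
  dplyr::bind_rows(rows)
}
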