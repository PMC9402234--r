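# Frequency summaries: genotype-positive frequencies per subpopulation and
# disease category, and the disease-category distribution of surviving
# variants. All stored values are full precision; rounding is presentation
# only.

#' Allele frequency
#'
#' @param ac alt (or minor) allele count, `0 <= ac <= an`.
#' @param an allele number, `> 0`.
#' @return `ac / an` at full precision.
#' @examples
#' allele_frequency(90, 2744) # 0.03279883...
#' @export
allele_frequency <- function(ac, an) {
  if (any(an <= 0)) stop("allele_frequency: an must be positive",
                         call. = FALSE)
  if (any(ac < 0 | ac > an)) {
    stop("allele_frequency: need 0 <= ac <= an", call. = FALSE)
  }
  ac / an
}

#' Genotype-positive frequency by subpopulation and disease category
#'
#' For each subpopulation and disease category, counts the alt alleles
#' (mode `"allele"`, the default) or the distinct carrier participants
#' (mode `"participant"`) over the surviving variants of that category, and
#' divides by the subpopulation's allele (`2n`) or participant (`n`)
#' denominator. The `"all"` category row aggregates over every surviving
#' variant, and the `"all"` subpopulation row over the whole cohort. In
#' allele mode a participant carrying two different surviving variants
#' contributes to both numerators; in participant mode they count once.
#' An empty subpopulation reports frequency 0 with its zero denominator.
#'
#' @param variants surviving variant records (must carry `gene`).
#' @param genotypes dosage matrix covering `variants$key`.
#' @param samples sample table (`sample_id`, `subpopulation`).
#' @param panel a `gene_panel` giving each gene's category.
#' @param mode `"allele"` or `"participant"`.
#' @return tibble with `category`, `subpopulation`, `numerator`,
#'   `denominator`, `frequency`.
#' @export
genotype_positive_frequency <- function(variants, genotypes, samples, panel,
                                        mode = c("allele", "participant")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "gene_panel"))
  if (!all(variants$gene %in% panel$genes$gene)) {
    stop("genotype_positive_frequency: variant gene(s) not in panel",
         call. = FALSE)
  }
  category <- panel$genes$category[match(variants$gene, panel$genes$gene)]
  subpops <- c(ACMGSF_SUBPOPS, "all")
  cats <- c("all", ACMGSF_CATEGORIES)
  rows <- list()
  for (cat in cats) {
    keys <- if (cat == "all") variants$key else variants$key[category == cat]
    dos <- genotypes[samples$sample_id, keys, drop = FALSE]
    for (sp in subpops) {
      in_sp <- if (sp == "all") rep(TRUE, nrow(samples)) else
        samples$subpopulation == sp
      n_sp <- sum(in_sp)
      if (mode == "allele") {
        num <- sum(dos[in_sp, , drop = FALSE], na.rm = TRUE)
        den <- 2L * n_sp
      } else {
        pos <- rowSums(dos[in_sp, , drop = FALSE] >= 1, na.rm = TRUE) > 0
        num <- sum(pos)
        den <- n_sp
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        category = cat, subpopulation = sp, numerator = as.integer(num),
        denominator = as.integer(den),
        frequency = if (den > 0) num / den else 0)
    }
  }
  dplyr::bind_rows(rows)
}

#' Disease-category distribution of surviving variants
#'
#' @param variants surviving variant records.
#' @param panel a `gene_panel`.
#' @return tibble with `category`, `n_variants`, `n_genes`, `fraction`
#'   (full precision) and `percent` (display value, rounded to the nearest
#'   integer).
#' @examples
#' # 21 cardiovascular variants of 74 total -> fraction 0.2837..., percent 28
#' @export
category_distribution <- function(variants, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (!all(variants$gene %in% panel$genes$gene)) {
    stop("category_distribution: variant gene(s) not in panel", call. = FALSE)
  }
  category <- panel$genes$category[match(variants$gene, panel$genes$gene)]
  total <- nrow(variants)
  out <- lapply(ACMGSF_CATEGORIES, function(cat) {
    sel <- category == cat
    tibble::tibble(category = cat, n_variants = sum(sel),
                   n_genes = length(unique(variants$gene[sel])),
                   fraction = if (total > 0) sum(sel) / total else 0)
  })
  out <- dplyr::bind_rows(out)
  out$percent <- round(100 * out$fraction)
  out
}

#' Genotype-positive participant rate
#'
#' The share of the cohort carrying at least one alternate allele of any
#' candidate variant, as a percentage at full precision (display convention:
#' one decimal).
#'
#' @param carriers number of genotype-positive participants.
#' @param cohort_n cohort size, `> 0`.
#' @return `100 * carriers / cohort_n` at full precision.
#' @examples
#' round(genotype_positive_rate(270, 6045), 1) # 4.5
#' @export
genotype_positive_rate <- function(carriers, cohort_n) {
  if (cohort_n <= 0) stop("genotype_positive_rate: cohort_n must be positive",
                          call. = FALSE)
  if (carriers < 0 || carriers > cohort_n) {
    stop("genotype_positive_rate: need 0 <= carriers <= cohort_n",
         call. = FALSE)
  }
  100 * carriers / cohort_n
}
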