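# Segregation-based candidate selection: significant cardiovascular
# association, at least two affected carriers, parental-history support, and
# exclusion of known-pathogenic carriers from the analysis.

#' Selection criteria
#'
#' Significance applies to the cardiovascular-rubric association only;
#' parental history is supporting evidence with its own carrier-count
#' threshold (a variant can be selected even when its parental-history
#' association is itself non-significant).
#'
#' @param alpha two-sided significance threshold for the CVD association.
#' @param min_cvd_carriers minimum CVD-positive carriers.
#' @param min_parental_history_carriers minimum carriers reporting parental
#'   heart disease.
#' @return a `selection_criteria` list.
#' @export
selection_criteria <- function(alpha = 0.05, min_cvd_carriers = 2,
                               min_parental_history_carriers = 2) {
  if (alpha <= 0 || alpha >= 1) {
    stop("selection_criteria: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (min_cvd_carriers < 1 || min_parental_history_carriers < 1) {
    stop("selection_criteria: carrier minima must be >= 1", call. = FALSE)
  }
  structure(list(alpha = alpha,
                 min_cvd_carriers = as.integer(min_cvd_carriers),
                 min_parental_history_carriers =
                   as.integer(min_parental_history_carriers)),
            class = "selection_criteria")
}

#' Exclude carriers of known pathogenic cardiovascular variants
#'
#' Samples carrying any listed known-pathogenic variant in a
#' cardiovascular-category gene are removed from downstream association and
#' selection. Entries for genes outside the panel are ignored with a
#' warning; listed variants absent from the genotype matrix have no
#' carriers in the cohort and are silently inert.
#'
#' @param samples sample table (`sample_id`, `subpopulation`).
#' @param genotypes dosage matrix for the cohort (all variants, not just
#'   cascade survivors).
#' @param known_pathogenic_path TSV with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gene` (and optionally `assertion`).
#' @param panel a `gene_panel`.
#' @return list with `samples` (reduced sample table) and `excluded`
#'   (character vector of removed sample ids).
#' @export
exclude_known_pathogenic_carriers <- function(samples, genotypes,
                                              known_pathogenic_path, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  kp <- readr::read_tsv(known_pathogenic_path,
                        col_types = readr::cols(chrom = "c", pos = "i",
                                                ref = "c", alt = "c",
                                                gene = "c",
                                                .default = "c"),
                        progress = FALSE)
  need_cols(kp, c("chrom", "pos", "ref", "alt", "gene"),
            "known-pathogenic table")
  unknown <- !kp$gene %in% panel$genes$gene
  if (any(unknown)) {
    warning("exclude_known_pathogenic_carriers: ignoring entries for ",
            "gene(s) not in panel: ",
            paste(unique(kp$gene[unknown]), collapse = ", "), call. = FALSE)
    kp <- kp[!unknown, ]
  }
  cat_of <- panel$genes$category[match(kp$gene, panel$genes$gene)]
  kp <- kp[cat_of == "cardiovascular", ]
  keys <- intersect(variant_key(kp$chrom, kp$pos - 1L, kp$ref, kp$alt),
                    colnames(genotypes))
  excluded <- character(0)
  if (length(keys) > 0) {
    dos <- genotypes[, keys, drop = FALSE]
    excluded <- rownames(genotypes)[rowSums(dos >= 1, na.rm = TRUE) > 0]
  }
  list(samples = samples[!samples$sample_id %in% excluded, ],
       excluded = excluded)
}

#' Merge per-definition association results into candidate profiles
#'
#' @param cvd_assoc tibble from [associate_variants()] under the CVD rubric.
#' @param parental_assoc tibble from [associate_variants()] under parental
#'   history.
#' @return tibble with `key`, `p_cvd`, `or_cvd`, `n_carriers`,
#'   `n_cvd_positive_carriers`, `n_parental_history_carriers` (variants
#'   missing either association are dropped).
#' @export
candidate_profiles <- function(cvd_assoc, parental_assoc) {
  cvd <- cvd_assoc[, c("key", "p_two_sided", "odds_ratio", "n_carriers",
                       "n_carrier_positive")]
  names(cvd) <- c("key", "p_cvd", "or_cvd", "n_carriers",
                  "n_cvd_positive_carriers")
  par <- parental_assoc[, c("key", "n_carrier_positive")]
  names(par) <- c("key", "n_parental_history_carriers")
  dplyr::inner_join(cvd, par, by = "key")
}

#' Select candidate variants for functional follow-up
#'
#' Applies the segregation criteria to candidate profiles and returns a
#' ranked ledger recording every criterion's value and pass/fail flag, so
#' near-misses are auditable. A variant is selected iff all three criteria
#' pass: `p_cvd < alpha`, `n_cvd_positive_carriers >= min_cvd_carriers`, and
#' `n_parental_history_carriers >= min_parental_history_carriers`.
#'
#' @param profiles tibble as from [candidate_profiles()] (columns `key`,
#'   `p_cvd`, `n_cvd_positive_carriers`, `n_parental_history_carriers`;
#'   extra columns are carried through).
#' @param criteria a [selection_criteria()].
#' @return `profiles` with logical columns `pass_alpha`, `pass_min_cvd`,
#'   `pass_min_parental` and `selected`, ranked by `p_cvd`.
#' @export
select_candidates <- function(profiles, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  need_cols(profiles, c("key", "p_cvd", "n_cvd_positive_carriers",
                        "n_parental_history_carriers"), "candidate profiles")
  out <- profiles
  out$pass_alpha <- out$p_cvd < criteria$alpha
  out$pass_min_cvd <- out$n_cvd_positive_carriers >= criteria$min_cvd_carriers
  out$pass_min_parental <-
    out$n_parental_history_carriers >= criteria$min_parental_history_carriers
  out$selected <- out$pass_alpha & out$pass_min_cvd & out$pass_min_parental
  out[order(out$p_cvd, out$key), ]
}
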