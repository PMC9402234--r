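# The eight-stage novel-variant prioritization cascade. Stages are pure
# predicates over annotated variant records plus cohort genotype/kinship
# context; the funnel records survivors per stage. The final surviving set is
# the intersection of all predicates, so stage order affects only the funnel
# counts, never the outcome.

#' Cascade parameters
#'
#' Defaults are the analysis thresholds: CADD >= 20 and GERP >= 3
#' (inclusive), cohort folded MAF < 0.001 (strict), and "unrelated" meaning
#' kinship coefficient phi <= 0.0884 (the conventional third-degree cut-off
#' of the KING threshold family). When filtering a scaled-down synthetic
#' bundle, pass the bundle's own `maf_threshold`.
#'
#' @param cadd_min minimum CADD phred score (inclusive).
#' @param gerp_min minimum GERP RS score (inclusive).
#' @param maf_threshold folded minor-allele-frequency bound (exclusive).
#' @param phi_threshold kinship coefficient above which two samples count as
#'   related.
#' @return list of parameters.
#' @export
cascade_params <- function(cadd_min = 20, gerp_min = 3,
                           maf_threshold = 0.001, phi_threshold = 0.0884) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5, phi_threshold >= 0,
            phi_threshold <= 0.5)
  list(cadd_min = cadd_min, gerp_min = gerp_min,
       maf_threshold = maf_threshold, phi_threshold = phi_threshold)
}

#' Keep variants inside the panel's coding regions
#'
#' A variant survives when its (0-based) position lies inside at least one
#' panel interval and its annotated gene is a panel gene.
#'
#' @param variants annotated variant records.
#' @param panel a `gene_panel`.
#' @return the surviving subset of `variants`.
#' @export
filter_panel_region <- function(variants, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  keep <- panel_contains(panel, variants$chrom, variants$pos) &
    variants$gene %in% panel$genes$gene
  variants[keep, ]
}

#' Keep variants absent from all eight databases
#'
#' Membership in any of dbSNP, gnomAD, TOPMed, 1000 Genomes, ExAC, GME
#' Variome, HGMD or ClinVar disqualifies a variant. All eight flags must be
#' populated; there is no three-valued logic.
#'
#' @param variants annotated variant records.
#' @return the surviving subset.
#' @export
filter_novel <- function(variants) {
  flags <- as.matrix(variants[, ACMGSF_DB_FLAGS])
  if (anyNA(flags)) {
    stop("filter_novel: unpopulated membership flag for ",
         variants$key[which(rowSums(is.na(flags)) > 0)[1]], call. = FALSE)
  }
  variants[rowSums(flags) == 0, ]
}

#' Keep predicted-deleterious, conserved variants
#'
#' Survival requires CADD >= `cadd_min` and GERP >= `gerp_min`, both
#' inclusive.
#'
#' @param variants annotated variant records.
#' @param cadd_min,gerp_min inclusive thresholds.
#' @return the surviving subset.
#' @export
filter_deleterious <- function(variants, cadd_min = 20, gerp_min = 3) {
  if (anyNA(variants$cadd) || anyNA(variants$gerp)) {
    stop("filter_deleterious: missing CADD/GERP score", call. = FALSE)
  }
  variants[variants$cadd >= cadd_min & variants$gerp >= gerp_min, ]
}

#' Keep rare variants (folded cohort MAF below threshold)
#'
#' The folded frequency is `min(AC, AN - AC) / AN` with AN counting
#' non-missing alleles only. Variants with AN = 0 are dropped with a
#' warning.
#'
#' @param variants annotated variant records.
#' @param genotypes dosage matrix covering `variants$key`.
#' @param maf_threshold exclusive upper bound (default the analysis'
#'   0.001).
#' @return the surviving subset.
#' @export
filter_frequency <- function(variants, genotypes, maf_threshold = 0.001) {
  cnt <- allele_counts(genotypes)
  i <- match(variants$key, cnt$key)
  stopifnot(!anyNA(i))
  ac <- cnt$ac[i]
  an <- cnt$an[i]
  if (any(an == 0)) {
    warning("filter_frequency: dropping ", sum(an == 0),
            " variant(s) with AN = 0", call. = FALSE)
  }
  maf <- ifelse(an == 0, Inf, pmin(ac, an - ac) / an)
  variants[maf < maf_threshold, ]
}

#' Remove singletons (cohort alt allele count < 2)
#'
#' A single homozygous carrier (AC = 2) survives this stage; a lone
#' heterozygote does not.
#'
#' @inheritParams filter_frequency
#' @return the surviving subset.
#' @export
filter_singletons <- function(variants, genotypes) {
  cnt <- allele_counts(genotypes)
  ac <- cnt$ac[match(variants$key, cnt$key)]
  variants[ac >= 2, ]
}

#' Require at least two unrelated carriers
#'
#' A variant survives when its carrier set (dosage >= 1) contains an
#' independent set of size >= 2 in the relatedness graph, whose edges join
#' sample pairs with kinship `phi > phi_threshold`. A size-2 independent set
#' exists exactly when some carrier pair is non-adjacent, so the exact
#' pairwise check is used. Carriers absent from the kinship graph are
#' treated as unrelated to everyone (with a warning).
#'
#' @inheritParams filter_frequency
#' @param kinship a `kinship_graph`.
#' @param phi_threshold relatedness cut-off (default 0.0884, third-degree).
#' @return the surviving subset.
#' @export
filter_unrelated_carriers <- function(variants, genotypes, kinship,
                                      phi_threshold = 0.0884) {
  stopifnot(inherits(kinship, "kinship_graph"))
  phi_of <- kinship_lookup(kinship)
  unseen <- character(0)
  keep <- vapply(variants$key, function(k) {
    carr <- carriers_of(genotypes, k)
    unseen <<- union(unseen, setdiff(carr, kinship$nodes))
    if (length(carr) < 2) return(FALSE)
    for (i in seq_len(length(carr) - 1)) {
      for (j in (i + 1):length(carr)) {
        if (phi_of(carr[i], carr[j]) <= phi_threshold) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  if (length(unseen) > 0) {
    warning("filter_unrelated_carriers: ", length(unseen),
            " carrier(s) absent from the kinship graph treated as unrelated",
            call. = FALSE)
  }
  variants[keep, ]
}

#' Keep moderate-impact variants, dropping intronic and loss-of-function
#' effects
#'
#' Survival requires impact MODERATE; intron variants and the
#' loss-of-function consequence set (stop gained/lost, start lost,
#' frameshift, splice acceptor/donor) are removed. An unknown effect term is
#' kept, with a warning, so new consequence vocabularies fail loudly rather
#' than silently dropping records.
#'
#' @param variants annotated variant records.
#' @return the surviving subset.
#' @export
filter_impact_effect <- function(variants) {
  known <- c("missense_variant", "intron_variant", "synonymous_variant",
             "inframe_deletion", "inframe_insertion", "5_prime_UTR_variant",
             "3_prime_UTR_variant", ACMGSF_LOF_EFFECTS)
  unknown <- setdiff(unique(variants$effect), known)
  if (length(unknown) > 0) {
    warning("filter_impact_effect: unknown effect term(s) kept: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop_effect <- variants$effect %in% c("intron_variant", ACMGSF_LOF_EFFECTS)
  variants[variants$impact == "MODERATE" & !drop_effect, ]
}

ACMGSF_STAGES <- c("panel_region", "novelty", "cadd", "gerp", "frequency",
                   "singleton", "unrelated_carriers", "impact_effect")

apply_stage <- function(stage, variants, genotypes, kinship, panel, params) {
  switch(stage,
    panel_region = filter_panel_region(variants, panel),
    novelty = filter_novel(variants),
    cadd = filter_deleterious(variants, params$cadd_min, -Inf),
    gerp = filter_deleterious(variants, -Inf, params$gerp_min),
    frequency = filter_frequency(variants, genotypes, params$maf_threshold),
    singleton = filter_singletons(variants, genotypes),
    unrelated_carriers = filter_unrelated_carriers(variants, genotypes,
                                                   kinship,
                                                   params$phi_threshold),
    impact_effect = filter_impact_effect(variants),
    stop("unknown stage: ", stage, call. = FALSE))
}

#' Run the full prioritization cascade
#'
#' Applies the eight filter stages in the canonical order (panel region,
#' novelty, CADD, GERP, MAF, singleton removal, unrelated carriers,
#' impact/effect) and returns the funnel. The funnel also reports, for each
#' stage, the marginal count of initial variants failing that predicate
#' alone.
#'
#' @param variants annotated variant records.
#' @param genotypes dosage matrix.
#' @param kinship a `kinship_graph`.
#' @param panel a `gene_panel`.
#' @param params a [cascade_params()].
#' @param stage_order stage permutation (funnel counts change; the surviving
#'   set does not).
#' @return a `filter_funnel`: tibble with `stage`, `n_surviving`,
#'   `n_dropped`, `n_fail_marginal`; attributes `initial` (count) and
#'   `surviving` (the final variant records).
#' @export
run_cascade <- function(variants, genotypes, kinship, panel,
                        params = cascade_params(),
                        stage_order = ACMGSF_STAGES) {
  stopifnot(setequal(stage_order, ACMGSF_STAGES))
  current <- variants
  n0 <- nrow(variants)
  n_surv <- integer(length(stage_order))
  for (s in seq_along(stage_order)) {
    current <- apply_stage(stage_order[s], current, genotypes, kinship,
                           panel, params)
    n_surv[s] <- nrow(current)
  }
  marginal <- vapply(stage_order, function(st) {
    n0 - nrow(apply_stage(st, variants, genotypes, kinship, panel, params))
  }, integer(1))
  funnel <- tibble::tibble(
    stage = stage_order,
    n_surviving = n_surv,
    n_dropped = c(n0, n_surv[-length(n_surv)]) - n_surv,
    n_fail_marginal = marginal)
  structure(funnel, class = c("filter_funnel", class(funnel)),
            initial = n0, surviving = current)
}

#' Surviving variant records of a funnel
#' @param funnel a `filter_funnel` from [run_cascade()].
#' @return tibble of surviving variant records.
#' @export
surviving_variants <- function(funnel) {
  attr(funnel, "surviving")
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("<filter_funnel> ", attr(x, "initial"), " variants in, ",
      nrow(attr(x, "surviving")), " surviving\n", sep = "")
  NextMethod()
}

#' Write a funnel report
#'
#' Emits the funnel as TSV and JSON plus the surviving variants as TSV.
#'
#' @param funnel a `filter_funnel`.
#' @param out_dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_funnel <- function(funnel, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(funnel_tsv = file.path(out_dir, "funnel.tsv"),
             funnel_json = file.path(out_dir, "funnel.json"),
             surviving = file.path(out_dir, "surviving_variants.tsv"))
  readr::write_tsv(tibble::as_tibble(funnel), paths[["funnel_tsv"]],
                   progress = FALSE)
  jsonlite::write_json(
    list(initial = attr(funnel, "initial"),
         stages = tibble::as_tibble(funnel),
         surviving_keys = surviving_variants(funnel)$key),
    paths[["funnel_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(surviving_variants(funnel), paths[["surviving"]],
                   progress = FALSE)
  invisible(paths)
}
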