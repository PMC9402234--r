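# End-to-end orchestration: read the five input surfaces, run the cascade,
# write frequency summaries, association tables and the selection ledger,
# and record a run manifest sufficient to replay the run exactly.

#' Run the full analysis end to end
#'
#' Identical inputs and parameters produce byte-identical outputs (the
#' manifest records input digests, parameters and package version, and
#' deliberately no timestamps). If a stage fails, the manifest is still
#' written, naming the failed stage, before the error propagates.
#'
#' @param inputs named list or vector of paths: `vcf`, `annotations`,
#'   `samples`, `kinship`, `phenotypes` (e.g. `$paths` from
#'   [simulate_cohort()]).
#' @param out_dir output directory.
#' @param panel gene panel.
#' @param params [cascade_params()]; pass the bundle's MAF threshold when
#'   filtering a scaled synthetic cohort.
#' @param criteria [selection_criteria()].
#' @param known_pathogenic_path optional TSV of known pathogenic variants;
#'   their cardiovascular-gene carriers are excluded from association and
#'   selection.
#' @param mode frequency counting mode, `"allele"` (default) or
#'   `"participant"`.
#' @return list with `funnel`, `frequency`, `categories`, `associations`
#'   (both definitions), `selection`, `excluded`, `manifest`, and `paths`.
#' @export
run_all <- function(inputs, out_dir, panel = acmg_panel(),
                    params = cascade_params(),
                    criteria = selection_criteria(),
                    known_pathogenic_path = NULL,
                    mode = c("allele", "participant")) {
  mode <- match.arg(mode)
  inputs <- unlist(inputs)
  need <- c("vcf", "annotations", "samples", "kinship", "phenotypes")
  missing_names <- setdiff(need, names(inputs))
  if (length(missing_names) > 0) {
    stop("configuration error: missing input path(s): ",
         paste(missing_names, collapse = ", "), call. = FALSE)
  }
  absent <- inputs[need][!file.exists(inputs[need])]
  if (length(absent) > 0) {
    stop("configuration error: input file(s) not found: ",
         paste(paste0(names(absent), " (", absent, ")"), collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "ingest"
  manifest_path <- file.path(out_dir, "manifest.json")
  counts <- list()
  on_fail <- function(e) {
    jsonlite::write_json(
      list(tool = "acmgsf",
           version = as.character(utils::packageVersion("acmgsf")),
           status = "failed", failed_stage = stage,
           error = conditionMessage(e),
           inputs = as.list(tools::md5sum(unname(inputs[need])))),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    cohort <- read_cohort(inputs[["vcf"]], inputs[["samples"]])
    variants <- attach_annotations(cohort$stubs, inputs[["annotations"]])
    kinship <- read_kinship(inputs[["kinship"]],
                            sample_ids = cohort$samples$sample_id)
    phenotypes <- read_phenotypes(inputs[["phenotypes"]])
    counts$samples <- nrow(cohort$samples)
    counts$variants_in <- nrow(variants)

    stage <- "exclude_known_pathogenic"
    excluded <- character(0)
    assoc_samples <- cohort$samples
    if (!is.null(known_pathogenic_path)) {
      ex <- exclude_known_pathogenic_carriers(cohort$samples,
                                              cohort$genotypes,
                                              known_pathogenic_path, panel)
      assoc_samples <- ex$samples
      excluded <- ex$excluded
    }
    counts$samples_excluded <- length(excluded)

    stage <- "cascade"
    funnel <- run_cascade(variants, cohort$genotypes, kinship, panel, params)
    surv <- surviving_variants(funnel)
    counts$variants_surviving <- nrow(surv)
    funnel_paths <- write_funnel(funnel, out_dir)

    stage <- "summarize"
    freq <- genotype_positive_frequency(surv, cohort$genotypes,
                                        cohort$samples, panel, mode)
    cats <- category_distribution(surv, panel)
    freq_path <- file.path(out_dir, "subpopulation_frequency.tsv")
    cats_path <- file.path(out_dir, "category_distribution.tsv")
    readr::write_tsv(freq, freq_path, progress = FALSE)
    readr::write_tsv(cats, cats_path, progress = FALSE)

    stage <- "associate"
    assoc_geno <- cohort$genotypes[assoc_samples$sample_id, , drop = FALSE]
    assoc_cvd <- associate_variants(surv$key, assoc_geno, phenotypes,
                                    "cvd_rubric")
    assoc_par <- associate_variants(surv$key, assoc_geno, phenotypes,
                                    "parental_history")
    assoc_path <- file.path(out_dir, "associations.tsv")
    readr::write_tsv(dplyr::bind_rows(assoc_cvd, assoc_par), assoc_path,
                     progress = FALSE)

    stage <- "select"
    profiles <- candidate_profiles(assoc_cvd, assoc_par)
    selection <- select_candidates(profiles, criteria)
    selection_path <- file.path(out_dir, "selection_ledger.tsv")
    readr::write_tsv(selection, selection_path, progress = FALSE)
    counts$variants_selected <- sum(selection$selected)

    stage <- "manifest"
    manifest <- list(
      tool = "acmgsf",
      version = as.character(utils::packageVersion("acmgsf")),
      status = "ok",
      inputs = as.list(tools::md5sum(unname(inputs[need]))),
      params = params,
      criteria = unclass(criteria),
      mode = mode,
      counts = counts)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    paths <- c(funnel_paths,
               frequency = freq_path, categories = cats_path,
               associations = assoc_path, selection = selection_path,
               manifest = manifest_path)
    list(funnel = funnel, frequency = freq, categories = cats,
         associations = list(cvd = assoc_cvd, parental = assoc_par),
         selection = selection, excluded = excluded, manifest = manifest,
         paths = paths)
  }, error = on_fail)
}
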