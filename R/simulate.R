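# Synthetic-cohort generator. Produces a full input bundle (VCF + four TSVs
# + truth table) whose decision structure matches what the prioritization
# cascade assumes: every planted variant is constructed to fail exactly one
# named filter stage (its "fate") and satisfy all the others, so the funnel
# and the final surviving set are known by construction. The generator
# targets the analysis' decision structure, not population-genetic realism
# (no LD, no realistic site-frequency spectrum, no admixture model).

ACMGSF_FATES <- c("fails_panel", "fails_novelty", "fails_cadd", "fails_gerp",
                  "fails_maf", "fails_singleton", "fails_unrelated",
                  "fails_impact_effect", "survives_all")

#' Phenotype simulation model
#'
#' Background prevalences and carrier effect sizes for the simulated
#' cardiovascular phenotype surfaces. Carrier status multiplies the
#' background odds of being CVD-positive (and of reporting parental heart
#' disease) by the configured odds ratio; `Inf` is the deterministic limit
#' in which every carrier is positive (carrier prevalence 1.0).
#'
#' @param p_cvd background probability of being CVD-positive under the
#'   phenotype rubric (abnormal ECG, or borderline ECG with symptoms).
#' @param p_abnormal_given_cvd among CVD-positives, probability the
#'   presentation is an abnormal ECG (otherwise borderline ECG + symptom).
#' @param p_borderline_bg background probability of a symptom-free
#'   borderline ECG among CVD-negatives.
#' @param p_chest_pain_bg background probability of chest pain among
#'   CVD-negatives with a normal ECG.
#' @param p_parental_bg background probability of reporting parental heart
#'   disease.
#' @param p_ecg_missing probability an ECG record is missing.
#' @param carrier_or odds ratio of CVD-positivity for carriers of planted
#'   high-effect variants (> 0; `Inf` = deterministic limit).
#' @param parental_or odds ratio of parental heart-disease history for the
#'   same carriers.
#' @return a `pheno_model` list.
#' @export
pheno_model <- function(p_cvd = 0.08, p_abnormal_given_cvd = 0.7,
                        p_borderline_bg = 0.1, p_chest_pain_bg = 0.08,
                        p_parental_bg = 0.15, p_ecg_missing = 0.02,
                        carrier_or = Inf, parental_or = Inf) {
  probs <- c(p_cvd = p_cvd, p_abnormal_given_cvd = p_abnormal_given_cvd,
             p_borderline_bg = p_borderline_bg,
             p_chest_pain_bg = p_chest_pain_bg,
             p_parental_bg = p_parental_bg)
  if (any(probs <= 0 | probs >= 1)) {
    stop("pheno_model: prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (p_ecg_missing < 0 || p_ecg_missing >= 1) {
    stop("pheno_model: p_ecg_missing must lie in [0, 1)", call. = FALSE)
  }
  if (carrier_or <= 0 || parental_or <= 0) {
    stop("pheno_model: odds ratios must be positive", call. = FALSE)
  }
  structure(list(p_cvd = p_cvd,
                 p_abnormal_given_cvd = p_abnormal_given_cvd,
                 p_borderline_bg = p_borderline_bg,
                 p_chest_pain_bg = p_chest_pain_bg,
                 p_parental_bg = p_parental_bg,
                 p_ecg_missing = p_ecg_missing,
                 carrier_or = carrier_or,
                 parental_or = parental_or),
            class = "pheno_model")
}

#' Synthetic cohort configuration
#'
#' Defaults describe a cohort scaled to one tenth of the study the pipeline
#' emulates: 600 samples drawn from six subpopulations with weights
#' proportional to the published subpopulation sizes (ADM 1180, AFR 92, GAR
#' 2311, PAR 1052, WEP 1372, SAS 38), a relatedness structure of small
#' families with first/second-degree kinship, and planted variants covering
#' all nine filter fates. Because the cohort is scaled down 10x, the
#' generator's default minor-allele-frequency planting threshold is the
#' analysis threshold scaled by the same factor (0.01 instead of 0.001):
#' below cohort size 1/threshold no variant can simultaneously clear the
#' singleton filter (AC >= 2) and stay under the MAF bound, which
#' [simulate_cohort()] reports as an explicit infeasibility error.
#'
#' @param n_samples cohort size.
#' @param subpop_weights named proportions over ADM, AFR, GAR, PAR, WEP, SAS
#'   (normalized internally).
#' @param fate_counts named integer vector: how many variants to plant per
#'   fate (see `ACMGSF_FATES` fates in the vignette).
#' @param n_high_or how many `survives_all` variants carry the phenotype
#'   effect (`carrier_or` of `pheno`); the rest are phenotype-null (OR 1).
#' @param maf_threshold MAF threshold the planting targets; pass the same
#'   value to the cascade when filtering this bundle.
#' @param n_carriers carriers planted per variant (heterozygous, from
#'   distinct families) for all fates except the three that control their own
#'   carrier structure (`fails_singleton`: 1 carrier; `fails_unrelated`: 2
#'   related carriers; `fails_maf`: enough carriers to reach the threshold).
#' @param n_families number of multi-member families; remaining samples are
#'   unrelated singletons.
#' @param family_sizes family sizes sampled uniformly from this set.
#' @param phi_values kinship coefficients sampled for within-family pairs.
#' @param miss_rate genotype missingness rate (applied to non-carrier cells
#'   so planted allele counts are preserved).
#' @param pheno a [pheno_model()].
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 600,
                              subpop_weights = c(ADM = 1180, AFR = 92,
                                                 GAR = 2311, PAR = 1052,
                                                 WEP = 1372, SAS = 38),
                              fate_counts = c(fails_panel = 5,
                                              fails_novelty = 5,
                                              fails_cadd = 5,
                                              fails_gerp = 5,
                                              fails_maf = 5,
                                              fails_singleton = 5,
                                              fails_unrelated = 5,
                                              fails_impact_effect = 5,
                                              survives_all = 6),
                              n_high_or = 3,
                              maf_threshold = 0.01,
                              n_carriers = 4,
                              n_families = 40,
                              family_sizes = 2:3,
                              phi_values = c(0.25, 0.125),
                              miss_rate = 0.01,
                              pheno = pheno_model(),
                              seed = 1L) {
  if (!setequal(names(subpop_weights), ACMGSF_SUBPOPS)) {
    stop("simulation_config: subpop_weights must be named over ",
         paste(ACMGSF_SUBPOPS, collapse = ", "), call. = FALSE)
  }
  if (any(subpop_weights < 0) || sum(subpop_weights) <= 0) {
    stop("simulation_config: invalid subpopulation weights", call. = FALSE)
  }
  subpop_weights <- subpop_weights[ACMGSF_SUBPOPS] / sum(subpop_weights)
  unknown <- setdiff(names(fate_counts), ACMGSF_FATES)
  if (length(unknown) > 0) {
    stop("simulation_config: unknown fate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fates <- setNames(integer(length(ACMGSF_FATES)), ACMGSF_FATES)
  fates[names(fate_counts)] <- as.integer(fate_counts)
  if (any(fates < 0)) stop("simulation_config: negative fate count",
                           call. = FALSE)
  if (n_high_or > fates[["survives_all"]]) {
    stop("simulation_config: n_high_or exceeds planted survivors",
         call. = FALSE)
  }
  if (maf_threshold <= 0 || maf_threshold >= 0.5) {
    stop("simulation_config: maf_threshold must lie in (0, 0.5)",
         call. = FALSE)
  }
  stopifnot(inherits(pheno, "pheno_model"))
  structure(list(n_samples = as.integer(n_samples),
                 subpop_weights = subpop_weights,
                 fate_counts = fates, n_high_or = as.integer(n_high_or),
                 maf_threshold = maf_threshold,
                 n_carriers = as.integer(n_carriers),
                 n_families = as.integer(n_families),
                 family_sizes = as.integer(family_sizes),
                 phi_values = phi_values, miss_rate = miss_rate,
                 pheno = pheno, seed = as.integer(seed)),
            class = "simulation_config")
}

# Derive independent sub-seeds (one per surface) from the global seed so a
# surface can be regenerated without replaying the others.
surface_seeds <- function(seed) {
  (as.double(seed) * 48271 + c(samples = 11, genotypes = 22,
                               phenotypes = 33)) %% 2147483647
}

#' Simulate a synthetic cohort bundle
#'
#' Generates samples, family/kinship structure, planted variants with
#' genotypes and annotations, and phenotype records, optionally writing the
#' exact file formats the readers consume. Deterministic given
#' `config$seed`: the same configuration produces byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir if non-`NULL`, directory to write the bundle into
#'   (`cohort.vcf`, `annotations.tsv`, `samples.tsv`, `kinship.tsv`,
#'   `phenotypes.tsv`, `truth.tsv`, `config.yaml`).
#' @param panel gene panel the variants are planted against.
#' @return list with in-memory surfaces (`genotypes`, `variants`, `samples`,
#'   `kinship`, `phenotypes`), the `truth` table (tibble `key`, `fate`,
#'   `carriers`, `or`), `paths` (named vector or `NULL`) and `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL, panel = acmg_panel()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  an_full <- 2L * n
  # feasibility: planted survivors must clear both the singleton filter and
  # the MAF bound; never silently adjust.
  if (config$n_carriers < 2) {
    stop("infeasible config: survives_all needs >= 2 carriers", call. = FALSE)
  }
  if (config$n_carriers / an_full >= config$maf_threshold) {
    stop("infeasible config: MAF < ", config$maf_threshold,
         " is impossible for AC = ", config$n_carriers, " at n = ", n,
         " (need n > ", ceiling(config$n_carriers / (2 * config$maf_threshold)),
         ")", call. = FALSE)
  }
  ac_maf <- as.integer(ceiling(config$maf_threshold * an_full))
  n_units_needed <- max(config$n_carriers, ac_maf)
  seeds <- surface_seeds(config$seed)

  # --- samples, families, kinship -------------------------------------------
  sam <- withr::with_seed(seeds[["samples"]], {
    ids <- sprintf("S%05d", seq_len(n))
    subpop <- sample(ACMGSF_SUBPOPS, n, replace = TRUE,
                     prob = config$subpop_weights)
    fam_sizes <- sample(config$family_sizes, config$n_families,
                        replace = TRUE)
    if (sum(fam_sizes) > n) {
      stop("infeasible config: families need more samples than the cohort",
           call. = FALSE)
    }
    members <- sample(ids, sum(fam_sizes))
    family <- setNames(rep(NA_character_, n), ids)
    off <- 0L
    edges <- list()
    for (f in seq_along(fam_sizes)) {
      fam <- members[(off + 1L):(off + fam_sizes[f])]
      off <- off + fam_sizes[f]
      family[fam] <- sprintf("F%03d", f)
      prs <- utils::combn(sort(fam), 2)
      edges[[f]] <- tibble::tibble(
        id1 = prs[1, ], id2 = prs[2, ],
        phi = sample(config$phi_values, ncol(prs), replace = TRUE))
    }
    # unrelated samples are their own family unit for carrier placement
    single <- is.na(family)
    family[single] <- paste0("U", ids[single])
    list(samples = tibble::tibble(sample_id = ids, subpopulation = subpop),
         family = family, edges = dplyr::bind_rows(edges))
  })
  kinship <- structure(list(edges = sam$edges,
                            nodes = unique(c(sam$edges$id1, sam$edges$id2))),
                       class = "kinship_graph")
  units <- split(names(sam$family), sam$family)
  if (length(units) < n_units_needed) {
    stop("infeasible config: not enough independent family units (",
         length(units), ") to place ", n_units_needed, " unrelated carriers",
         call. = FALSE)
  }

  # --- variants and genotypes -----------------------------------------------
  gen <- withr::with_seed(seeds[["genotypes"]], {
    total <- sum(config$fate_counts)
    fate <- rep(names(config$fate_counts), config$fate_counts)
    geno <- matrix(0L, nrow = n, ncol = total,
                   dimnames = list(sam$samples$sample_id, NULL))
    rows <- vector("list", total)
    carriers_str <- character(total)
    or <- rep(1, total)
    high_left <- config$n_high_or
    used_pos <- character(0)
    bases <- c("A", "C", "G", "T")
    multi_fams <- names(units)[lengths(units) >= 2]
    for (v in seq_len(total)) {
      f <- fate[v]
      gi <- sample.int(nrow(panel$genes), 1)
      gene <- panel$genes$gene[gi]
      ivs <- panel$intervals[panel$intervals$gene == gene, ]
      iv <- ivs[sample.int(nrow(ivs), 1), ]
      if (f == "fails_panel") {
        # outside every panel interval, on the same contig
        repeat {
          pos <- iv$end + sample.int(50000L, 1) + 4999L
          if (!panel_contains(panel, iv$chrom, pos) &&
              !(paste(iv$chrom, pos) %in% used_pos)) break
        }
      } else {
        repeat {
          pos <- iv$start + sample.int(iv$end - iv$start, 1) - 1L
          if (!(paste(iv$chrom, pos) %in% used_pos)) break
        }
      }
      used_pos <- c(used_pos, paste(iv$chrom, pos))
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      cadd <- round(runif(1, 20, 40), 2)
      gerp <- round(runif(1, 3, 6), 2)
      effect <- "missense_variant"
      impact <- "MODERATE"
      flags <- setNames(rep(FALSE, length(ACMGSF_DB_FLAGS)), ACMGSF_DB_FLAGS)
      if (f == "fails_novelty") flags[sample(ACMGSF_DB_FLAGS, 1)] <- TRUE
      if (f == "fails_cadd") cadd <- round(runif(1, 5, 19.5), 2)
      if (f == "fails_gerp") gerp <- round(runif(1, -3, 2.5), 2)
      if (f == "fails_impact_effect") {
        pick <- sample(3, 1)
        effect <- c("intron_variant", "stop_gained",
                    "frameshift_variant")[pick]
        impact <- c("MODIFIER", "HIGH", "HIGH")[pick]
      }
      carr <- switch(f,
        fails_singleton = sample(unlist(lapply(units, `[`, 1)), 1),
        fails_unrelated = {
          fam <- units[[sample(multi_fams, 1)]]
          sample(fam, 2)
        },
        fails_maf = vapply(units[sample(names(units), ac_maf)],
                           function(u) sample(u, 1), character(1)),
        vapply(units[sample(names(units), config$n_carriers)],
               function(u) sample(u, 1), character(1)))
      geno[carr, v] <- 1L
      if (f == "survives_all" && high_left > 0) {
        or[v] <- config$pheno$carrier_or
        high_left <- high_left - 1
      }
      carriers_str[v] <- paste(sort(carr), collapse = ";")
      rows[[v]] <- tibble::tibble(
        chrom = iv$chrom, pos = pos, ref = ref, alt = alt, gene = gene,
        effect = effect, impact = impact, cadd = cadd, gerp = gerp,
        !!!as.list(flags))
    }
    variants <- dplyr::bind_rows(rows)
    variants$key <- variant_key(variants$chrom, variants$pos, variants$ref,
                                variants$alt)
    colnames(geno) <- variants$key
    # missingness on non-carrier cells only, so planted AC is preserved
    if (config$miss_rate > 0) {
      miss <- matrix(runif(length(geno)) < config$miss_rate, nrow = n)
      geno[miss & geno == 0L] <- NA_integer_
    }
    truth <- tibble::tibble(key = variants$key, fate = fate,
                            carriers = carriers_str, or = or)
    # sort variants as a VCF would be
    ordv <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[ordv, c("key", "chrom", "pos", "ref", "alt", "gene",
                                 "effect", "impact", "cadd", "gerp",
                                 ACMGSF_DB_FLAGS)]
    list(variants = variants, geno = geno[, variants$key, drop = FALSE],
         truth = truth[ordv, ])
  })

  # --- phenotypes -----------------------------------------------------------
  high_keys <- gen$truth$key[gen$truth$fate == "survives_all" &
                               gen$truth$or > 1]
  carrier <- rep(FALSE, n)
  if (length(high_keys) > 0) {
    dos <- gen$geno[, high_keys, drop = FALSE]
    carrier <- rowSums(dos >= 1, na.rm = TRUE) > 0
  }
  phenotypes <- simulate_phenotypes(carrier, config$pheno,
                                    seed = seeds[["phenotypes"]],
                                    sample_ids = sam$samples$sample_id)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
               annotations = file.path(out_dir, "annotations.tsv"),
               samples = file.path(out_dir, "samples.tsv"),
               kinship = file.path(out_dir, "kinship.tsv"),
               phenotypes = file.path(out_dir, "phenotypes.tsv"),
               truth = file.path(out_dir, "truth.tsv"),
               config = file.path(out_dir, "config.yaml"))
    write_cohort_vcf(gen$geno, gen$variants, paths[["vcf"]])
    write_annotations_tsv(gen$variants, paths[["annotations"]])
    write_samples_tsv(sam$samples, paths[["samples"]])
    write_kinship_tsv(kinship, paths[["kinship"]])
    write_phenotypes_tsv(phenotypes, paths[["phenotypes"]])
    readr::write_tsv(gen$truth, paths[["truth"]], progress = FALSE)
    cfg <- unclass(config)
    cfg$pheno <- unclass(cfg$pheno)
    cfg$subpop_weights <- as.list(cfg$subpop_weights)
    cfg$fate_counts <- as.list(cfg$fate_counts)
    yaml::write_yaml(cfg, paths[["config"]])
  }
  list(genotypes = gen$geno, variants = gen$variants, samples = sam$samples,
       kinship = kinship, phenotypes = phenotypes, truth = gen$truth,
       paths = paths, config = config)
}

#' Simulate phenotype records for a carrier vector
#'
#' Draws CVD-positive status per sample from the logistic-odds model
#' (`P(positive | carrier) = OR * odds_bg / (1 + OR * odds_bg)`), then
#' realizes it as concrete ECG/symptom records consistent with the
#' cardiovascular rubric: positives present as abnormal ECG or as borderline
#' ECG with chest pain or a self-reported condition; negatives as normal ECG
#' (possibly with incidental chest pain) or symptom-free borderline ECG.
#' Parental heart-disease history is drawn analogously with its own odds
#' ratio.
#'
#' @param carrier logical vector: carries a planted high-effect variant.
#' @param model a [pheno_model()].
#' @param seed integer seed.
#' @param sample_ids optional ids (defaults to P00001, ...).
#' @return tibble of phenotype records (same columns as
#'   [read_phenotypes()]).
#' @export
simulate_phenotypes <- function(carrier, model, seed,
                                sample_ids = NULL) {
  stopifnot(inherits(model, "pheno_model"), is.logical(carrier))
  carrier <- unname(carrier)
  n <- length(carrier)
  if (is.null(sample_ids)) sample_ids <- sprintf("P%05d", seq_len(n))
  withr::with_seed(seed, {
    odds_bg <- model$p_cvd / (1 - model$p_cvd)
    p_pos <- ifelse(carrier,
                    if (is.infinite(model$carrier_or)) 1 else
                      (model$carrier_or * odds_bg) /
                        (1 + model$carrier_or * odds_bg),
                    model$p_cvd)
    cvd <- runif(n) < p_pos
    abn <- runif(n) < model$p_abnormal_given_cvd
    ecg <- rep("normal", n)
    chest <- rep(FALSE, n)
    cond <- rep("", n)
    ecg[cvd & abn] <- "abnormal"
    ecg[cvd & !abn] <- "borderline"
    symptom_is_pain <- runif(n) < 0.7
    chest[cvd & !abn & symptom_is_pain] <- TRUE
    cond[cvd & !abn & !symptom_is_pain] <- "angina"
    # background presentations that the rubric must NOT count as positive
    borderline_bg <- !cvd & runif(n) < model$p_borderline_bg
    ecg[borderline_bg] <- "borderline"
    chest[!cvd & !borderline_bg & runif(n) < model$p_chest_pain_bg] <- TRUE
    odds_par <- model$p_parental_bg / (1 - model$p_parental_bg)
    p_par <- ifelse(carrier,
                    if (is.infinite(model$parental_or)) 1 else
                      (model$parental_or * odds_par) /
                        (1 + model$parental_or * odds_par),
                    model$p_parental_bg)
    parental <- runif(n) < p_par
    ecg[runif(n) < model$p_ecg_missing] <- "missing"
    tibble::tibble(sample_id = sample_ids, ecg = ecg, chest_pain = chest,
                   parental_heart_disease = parental,
                   self_reported_conditions = cond)
  })
}
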