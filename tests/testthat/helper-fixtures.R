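# Fixture builders: everything is constructed in code at test time.

DBF <- c("dbsnp", "gnomad", "topmed", "kg1000", "exac", "gme", "hgmd",
         "clinvar")

# An annotated variant record row with sensible pass-everything defaults.
make_variant <- function(key = "1:99:A:G", chrom = NULL, pos = NULL,
                         ref = NULL, alt = NULL, gene = "DSP",
                         effect = "missense_variant", impact = "MODERATE",
                         cadd = 25, gerp = 5, flags = FALSE) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  flag_vals <- if (length(flags) == 1) rep(flags, 8) else flags
  names(flag_vals) <- DBF
  tibble::tibble(key = key,
                 chrom = if (is.null(chrom)) parts[1] else chrom,
                 pos = if (is.null(pos)) as.integer(parts[2]) else pos,
                 ref = if (is.null(ref)) parts[3] else ref,
                 alt = if (is.null(alt)) parts[4] else alt,
                 gene = gene, effect = effect, impact = impact,
                 cadd = cadd, gerp = gerp, !!!as.list(flag_vals))
}

# Dosage matrix from a named list key -> integer vector over sample ids.
make_geno <- function(sample_ids, dosages) {
  m <- do.call(cbind, dosages)
  rownames(m) <- sample_ids
  storage.mode(m) <- "integer"
  m
}

# Kinship graph through the reader (also exercises IO).
make_kinship <- function(id1 = character(), id2 = character(),
                         phi = double()) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(tibble::tibble(id1 = id1, id2 = id2, phi = phi), path)
  read_kinship(path)
}

# Phenotype record builder.
make_pheno <- function(sample_id, ecg = "normal", chest_pain = FALSE,
                       parental = FALSE, conditions = "") {
  tibble::tibble(sample_id = sample_id,
                 ecg = ecg,
                 chest_pain = chest_pain,
                 parental_heart_disease = parental,
                 self_reported_conditions = conditions)
}

# Small cohort simulation used by several files; feasible at n = 150+ with
# the scaled MAF threshold 0.02.
small_config <- function(seed, n_samples = 200, ...) {
  simulation_config(n_samples = n_samples, maf_threshold = 0.02,
                    n_carriers = 3, n_families = 20, seed = seed, ...)
}
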