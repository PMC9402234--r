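# Cohort IO: readers and writers for the five input surfaces (VCF genotypes,
# annotation TSV, sample TSV, kinship TSV, phenotype TSV). Positions are
# 1-based in files (VCF/TSV dialect) and 0-based internally; multiallelic VCF
# records are split so every internal record has exactly one alt allele.

#' Read cohort genotypes and sample labels
#'
#' Reads a VCF 4.2 file (GT format field required; `/` and `|` separators
#' both accepted, phase ignored) and a sample table, returning the genotype
#' matrix as alt-allele dosages, variant record stubs, and sample records.
#' Multiallelic sites are split into one record per alt allele; genotypes
#' containing a missing allele (`.`) become missing dosages.
#'
#' @param vcf_path path to a VCF file (plain text or bgzip).
#' @param samples_path path to a TSV with columns `sample_id`,
#'   `subpopulation` (one of ADM, AFR, GAR, PAR, WEP, SAS).
#' @return list with `genotypes` (integer matrix samples x variants, `NA` =
#'   missing, column names are variant keys), `stubs` (tibble `key`, `chrom`,
#'   `pos` 0-based, `ref`, `alt`), and `samples` (tibble `sample_id`,
#'   `subpopulation`).
#' @export
read_cohort <- function(vcf_path, samples_path) {
  samples <- read_samples(samples_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-record VCF
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  chrom <- fix[, "CHROM"]
  pos1 <- as.integer(fix[, "POS"])
  for (ch in unique(chrom)) {
    p <- pos1[chrom == ch]
    if (is.unsorted(p)) {
      stop("unsorted VCF: positions on contig '", ch,
           "' are not non-decreasing", call. = FALSE)
    }
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT format field", call. = FALSE)
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  vcf_samples <- colnames(gt)
  missing_samples <- setdiff(samples$sample_id, vcf_samples)
  if (length(missing_samples) > 0) {
    stop("sample mismatch: sample table id(s) absent from VCF: ",
         paste(head(missing_samples, 5), collapse = ", "), call. = FALSE)
  }
  gt <- gt[, samples$sample_id, drop = FALSE]

  keys <- character(0)
  stub_rows <- list()
  dosage_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[i, ], "[/|]")
    for (k in seq_along(alts)) {
      if (alts[k] == fix[i, "REF"]) {
        stop("malformed record: ref equals alt at ", chrom[i], ":", pos1[i],
             call. = FALSE)
      }
      dos <- vapply(alleles, function(a) {
        if (length(a) != 2 || anyNA(a) || any(a == ".")) return(NA_integer_)
        if (!all(grepl("^[0-9]+$", a))) {
          stop("malformed GT call in VCF", call. = FALSE)
        }
        sum(a == as.character(k))
      }, integer(1))
      key <- variant_key(chrom[i], pos1[i] - 1L, fix[i, "REF"], alts[k])
      keys <- c(keys, key)
      stub_rows[[length(stub_rows) + 1L]] <- tibble::tibble(
        key = key, chrom = chrom[i], pos = pos1[i] - 1L,
        ref = fix[i, "REF"], alt = alts[k])
      dosage_rows[[length(dosage_rows) + 1L]] <- dos
    }
  }
  if (anyDuplicated(keys)) {
    stop("duplicate variant record(s) in VCF: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  genotypes <- do.call(cbind, dosage_rows)
  dimnames(genotypes) <- list(samples$sample_id, keys)
  list(genotypes = genotypes,
       stubs = dplyr::bind_rows(stub_rows),
       samples = samples)
}

read_samples <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need_cols(tab, c("sample_id", "subpopulation"), "sample table")
  bad <- !tab$subpopulation %in% ACMGSF_SUBPOPS
  if (any(bad)) {
    stop("sample table: unknown subpopulation label(s): ",
         paste(unique(tab$subpopulation[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("sample table: duplicated sample id(s)", call. = FALSE)
  }
  tibble::as_tibble(tab[, c("sample_id", "subpopulation")])
}

need_cols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss) > 0) {
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Attach per-variant annotations to VCF stubs
#'
#' Joins the side annotation table (keyed by chrom, 1-based pos, ref, alt)
#' onto variant stubs from [read_cohort()]. Every stub must match exactly one
#' annotation row; all eight database-membership flags, CADD, GERP, gene,
#' effect and impact must be populated.
#'
#' @param stubs tibble from [read_cohort()].
#' @param annotations_path TSV with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gene`, `effect`, `impact`, `cadd`, `gerp`, and logical flags
#'   `dbsnp`, `gnomad`, `topmed`, `kg1000`, `exac`, `gme`, `hgmd`, `clinvar`.
#' @return tibble of full variant records (one row per alt allele).
#' @export
attach_annotations <- function(stubs, annotations_path) {
  ann <- readr::read_tsv(
    annotations_path,
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", gene = "c",
      effect = "c", impact = "c", cadd = "d", gerp = "d",
      .default = "l"),
    progress = FALSE)
  need_cols(ann, c("chrom", "pos", "ref", "alt", "gene", "effect", "impact",
                   "cadd", "gerp", ACMGSF_DB_FLAGS), "annotation table")
  ann$key <- variant_key(ann$chrom, ann$pos - 1L, ann$ref, ann$alt)
  dup <- ann$key[duplicated(ann$key)]
  if (length(dup) > 0) {
    stop("annotation table: duplicate row(s) for variant key(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  i <- match(stubs$key, ann$key)
  if (anyNA(i)) {
    stop("annotation table: no row for variant key(s): ",
         paste(head(stubs$key[is.na(i)], 5), collapse = ", "), call. = FALSE)
  }
  ann <- ann[i, ]
  bad_imp <- !ann$impact %in% ACMGSF_IMPACTS
  if (any(bad_imp)) {
    stop("annotation table: unknown impact class '",
         ann$impact[which(bad_imp)[1]], "' for ", ann$key[which(bad_imp)[1]],
         call. = FALSE)
  }
  for (col in c("cadd", "gerp")) {
    if (anyNA(ann[[col]])) {
      stop("annotation table: missing ", col, " score for ",
           ann$key[which(is.na(ann[[col]]))[1]], call. = FALSE)
    }
  }
  for (col in ACMGSF_DB_FLAGS) {
    if (anyNA(ann[[col]])) {
      stop("annotation table: unpopulated ", col, " membership flag for ",
           ann$key[which(is.na(ann[[col]]))[1]], call. = FALSE)
    }
  }
  tibble::as_tibble(cbind(
    stubs,
    ann[, c("gene", "effect", "impact", "cadd", "gerp", ACMGSF_DB_FLAGS)]))
}

#' Read the phenotype table
#'
#' ECG values are case-folded into the normal/borderline/abnormal/missing
#' vocabulary (empty or absent values become missing).
#'
#' @param path TSV with columns `sample_id`, `ecg`, `chest_pain`,
#'   `parental_heart_disease`, `self_reported_conditions`
#'   (semicolon-separated terms, possibly empty).
#' @return tibble of phenotype records.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(sample_id = "c", ecg = "c", chest_pain = "l",
                            parental_heart_disease = "l",
                            self_reported_conditions = "c"),
    progress = FALSE)
  need_cols(tab, c("sample_id", "ecg", "chest_pain", "parental_heart_disease",
                   "self_reported_conditions"), "phenotype table")
  ecg <- tolower(trimws(ifelse(is.na(tab$ecg), "missing", tab$ecg)))
  ecg[ecg == ""] <- "missing"
  bad <- !ecg %in% ACMGSF_ECG_LEVELS
  if (any(bad)) {
    stop("phenotype table: unknown ecg value '", tab$ecg[which(bad)[1]],
         "' for sample ", tab$sample_id[which(bad)[1]], call. = FALSE)
  }
  tab$ecg <- ecg
  tab$self_reported_conditions[is.na(tab$self_reported_conditions)] <- ""
  tibble::as_tibble(tab)
}

#' Read the pairwise kinship table
#'
#' Edges are symmetrized (stored with a canonical id ordering) and validated:
#' kinship coefficients must lie in `[0, 0.5]` and self-pairs are rejected.
#' Unlisted pairs are implicitly unrelated (phi = 0).
#'
#' @param path TSV with columns `id1`, `id2`, `phi`.
#' @param sample_ids optional vector of known sample ids; ids outside it are
#'   rejected.
#' @return a `kinship_graph`: list with `edges` (tibble `id1`, `id2`, `phi`,
#'   id1 < id2) and `nodes` (character vector).
#' @export
read_kinship <- function(path, sample_ids = NULL) {
  tab <- readr::read_tsv(path,
                         col_types = readr::cols(id1 = "c", id2 = "c",
                                                 phi = "d"),
                         progress = FALSE)
  need_cols(tab, c("id1", "id2", "phi"), "kinship table")
  if (any(tab$id1 == tab$id2)) {
    stop("kinship table: self-pair for sample ",
         tab$id1[which(tab$id1 == tab$id2)[1]], call. = FALSE)
  }
  if (any(is.na(tab$phi) | tab$phi < 0 | tab$phi > 0.5)) {
    i <- which(is.na(tab$phi) | tab$phi < 0 | tab$phi > 0.5)[1]
    stop("kinship table: phi out of [0, 0.5] for pair (", tab$id1[i], ", ",
         tab$id2[i], "): ", tab$phi[i], call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    unknown <- setdiff(unique(c(tab$id1, tab$id2)), sample_ids)
    if (length(unknown) > 0) {
      stop("kinship table: unknown sample id(s): ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  a <- pmin(tab$id1, tab$id2)
  b <- pmax(tab$id1, tab$id2)
  edges <- tibble::tibble(id1 = a, id2 = b, phi = tab$phi)
  pair <- paste(edges$id1, edges$id2, sep = "\r")
  if (anyDuplicated(pair)) {
    keep <- !duplicated(pair)
    agree <- tapply(edges$phi, pair, function(x) diff(range(x)) < 1e-12)
    if (!all(agree)) {
      stop("kinship table: conflicting phi for duplicated pair(s)",
           call. = FALSE)
    }
    edges <- edges[keep, ]
  }
  structure(list(edges = edges, nodes = unique(c(edges$id1, edges$id2))),
            class = "kinship_graph")
}

#' @export
print.kinship_graph <- function(x, ...) {
  cat("<kinship_graph> ", length(x$nodes), " related samples, ",
      nrow(x$edges), " pairs\n", sep = "")
  invisible(x)
}

# Fast phi lookup environment keyed "id1\rid2" with id1 < id2.
kinship_lookup <- function(kinship) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  e <- kinship$edges
  for (i in seq_len(nrow(e))) {
    assign(paste(e$id1[i], e$id2[i], sep = "\r"), e$phi[i], envir = env)
  }
  function(a, b) {
    k <- paste(min(a, b), max(a, b), sep = "\r")
    if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else 0
  }
}

# Cohort alt-allele count (AC) and non-missing allele number (AN) per variant.
#' Per-variant cohort allele counts
#'
#' @param genotypes dosage matrix from [read_cohort()].
#' @return tibble with `key`, `ac` (alt allele count) and `an` (number of
#'   non-missing alleles; missing genotypes are excluded from the
#'   denominator).
#' @export
allele_counts <- function(genotypes) {
  tibble::tibble(
    key = colnames(genotypes),
    ac = as.integer(colSums(genotypes, na.rm = TRUE)),
    an = 2L * as.integer(colSums(!is.na(genotypes))))
}

# Carrier ids (dosage >= 1) of one variant.
carriers_of <- function(genotypes, key) {
  dos <- genotypes[, key]
  rownames(genotypes)[!is.na(dos) & dos >= 1]
}

# Writers ---------------------------------------------------------------------
# All writers emit TSV (or VCF 4.2) with a stable column order and LF line
# endings so that identical inputs give byte-identical files.

#' Write a genotype matrix as VCF 4.2
#'
#' One biallelic record per variant (records sorted by contig then position),
#' GT-only FORMAT. Used by the synthetic-cohort generator and the funnel's
#' surviving-variant output.
#'
#' @param genotypes dosage matrix (samples x variants).
#' @param stubs tibble with `key`, `chrom`, `pos` (0-based), `ref`, `alt`
#'   covering the matrix columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(genotypes, stubs, path) {
  stopifnot(all(colnames(genotypes) %in% stubs$key))
  stubs <- stubs[match(colnames(genotypes), stubs$key), ]
  ord <- order(stubs$chrom, stubs$pos, stubs$ref, stubs$alt)
  stubs <- stubs[ord, ]
  genotypes <- genotypes[, stubs$key, drop = FALSE]
  gt_str <- matrix("./.", nrow = ncol(genotypes), ncol = nrow(genotypes))
  codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    dos <- genotypes[, j]
    gt_str[j, !is.na(dos)] <- codes[dos[!is.na(dos)] + 1L]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=acmgsf",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(nrow(stubs)), function(j) {
    paste(c(stubs$chrom[j], stubs$pos[j] + 1L, ".", stubs$ref[j],
            stubs$alt[j], ".", "PASS", ".", "GT", gt_str[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Write an annotation table
#' @param variants full variant records (as from [attach_annotations()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(variants, path) {
  out <- variants[, c("chrom", "pos", "ref", "alt", "gene", "effect",
                      "impact", "cadd", "gerp", ACMGSF_DB_FLAGS)]
  out$pos <- out$pos + 1L # files carry 1-based positions
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a sample table
#' @param samples tibble `sample_id`, `subpopulation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples_tsv <- function(samples, path) {
  readr::write_tsv(samples[, c("sample_id", "subpopulation")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write a kinship table
#' @param kinship a `kinship_graph` or an edge tibble `id1`, `id2`, `phi`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(kinship, path) {
  edges <- if (inherits(kinship, "kinship_graph")) kinship$edges else kinship
  readr::write_tsv(edges[, c("id1", "id2", "phi")], path, progress = FALSE)
  invisible(path)
}

#' Write a phenotype table
#' @param phenotypes tibble as returned by [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  readr::write_tsv(
    phenotypes[, c("sample_id", "ecg", "chest_pain",
                   "parental_heart_disease", "self_reported_conditions")],
    path, progress = FALSE)
  invisible(path)
}
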