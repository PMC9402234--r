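# Gene panel: the 59 ACMG secondary-findings genes, their coding intervals
# and the five-way disease-category mapping used throughout the pipeline.
# Intervals are half-open and 0-based internally (BED convention).

#' Load a gene panel configuration
#'
#' Reads a YAML panel description (gene symbols and disease categories, plus
#' the name of a companion BED file of coding intervals) and validates it:
#' every gene must carry exactly one known category and at least one interval
#' with `start < end`.
#'
#' @param config_path path to the panel YAML. The YAML must contain
#'   `genes:` (list of `symbol`/`category` pairs) and `intervals_bed:`
#'   (BED path, resolved relative to the YAML unless absolute).
#' @param bed_path optional override for the intervals BED.
#' @return a `gene_panel` object: list with `genes` (tibble `gene`,
#'   `category`) and `intervals` (tibble `gene`, `chrom`, `start`, `end`;
#'   half-open 0-based).
#' @examples
#' panel <- load_gene_panel(acmgsf_panel_config())
#' nrow(panel$genes) # 59
#' @export
load_gene_panel <- function(config_path, bed_path = NULL) {
  if (!file.exists(config_path)) {
    stop("panel config not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$genes) || length(cfg$genes) == 0) {
    stop("panel validation: config lists no genes", call. = FALSE)
  }
  rows <- lapply(seq_along(cfg$genes), function(i) {
    g <- cfg$genes[[i]]
    if (is.null(g$symbol) || !nzchar(g$symbol)) {
      stop("panel validation: gene entry ", i, " has no symbol", call. = FALSE)
    }
    if (is.null(g$category)) {
      stop("panel validation: gene '", g$symbol, "' has no category",
           call. = FALSE)
    }
    if (!g$category %in% ACMGSF_CATEGORIES) {
      stop("panel validation: gene '", g$symbol, "' has unknown category '",
           g$category, "'", call. = FALSE)
    }
    tibble::tibble(gene = g$symbol, category = g$category)
  })
  genes <- dplyr::bind_rows(rows)
  if (anyDuplicated(genes$gene)) {
    stop("panel validation: duplicated gene symbol(s): ",
         paste(unique(genes$gene[duplicated(genes$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(bed_path)) {
    if (is.null(cfg$intervals_bed)) {
      stop("panel validation: no intervals_bed in config and no bed_path given",
           call. = FALSE)
    }
    bed_path <- cfg$intervals_bed
    if (!grepl("^/", bed_path)) {
      bed_path <- file.path(dirname(config_path), bed_path)
    }
  }
  intervals <- read_panel_bed(bed_path)
  missing <- setdiff(genes$gene, intervals$gene)
  if (length(missing) > 0) {
    stop("panel validation: gene(s) without intervals: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(intervals$gene, genes$gene)
  if (length(orphan) > 0) {
    stop("panel validation: interval(s) for unlisted gene(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(genes = genes, intervals = intervals), class = "gene_panel")
}

read_panel_bed <- function(bed_path) {
  if (!file.exists(bed_path)) {
    stop("panel intervals BED not found: ", bed_path, call. = FALSE)
  }
  bed <- readr::read_tsv(bed_path,
                         col_names = c("chrom", "start", "end", "gene"),
                         col_types = "ciic", progress = FALSE)
  bad <- bed$start >= bed$end
  if (any(bad)) {
    i <- which(bad)[1]
    stop("panel validation: degenerate interval (start >= end) for gene '",
         bed$gene[i], "' at ", bed$chrom[i], ":", bed$start[i], "-",
         bed$end[i], call. = FALSE)
  }
  if (any(bed$start < 0)) {
    stop("panel validation: negative interval start", call. = FALSE)
  }
  bed
}

#' Path to the shipped default panel configuration
#'
#' The default panel encodes the ACMG secondary-findings v2.0 list of 59
#' genes grouped into five disease categories (cardiovascular, cancers,
#' familial hypercholesteremia, malignant hyperthermia, others). Its coding
#' intervals are synthetic placeholders (the companion file is named
#' accordingly); real transcript models can be supplied as a drop-in BED.
#'
#' @return path to the YAML config inside the installed package.
#' @export
acmgsf_panel_config <- function() {
  system.file("extdata", "acmg59_panel.yaml", package = "acmgsf",
              mustWork = TRUE)
}

#' Load the shipped default 59-gene panel
#'
#' @return a `gene_panel` (see [load_gene_panel()]).
#' @export
acmg_panel <- function() {
  load_gene_panel(acmgsf_panel_config())
}

#' Disease category of a panel gene
#'
#' @param panel a `gene_panel`.
#' @param gene a single gene symbol.
#' @return the gene's category (one of cardiovascular, cancers,
#'   familial_hypercholesteremia, malignant_hyperthermia, others).
#' @examples
#' category_of(acmg_panel(), "DSP") # "cardiovascular"
#' @export
category_of <- function(panel, gene) {
  stopifnot(inherits(panel, "gene_panel"), length(gene) == 1)
  i <- match(gene, panel$genes$gene)
  if (is.na(i)) {
    stop("gene '", gene, "' is not in the panel", call. = FALSE)
  }
  panel$genes$category[i]
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", nrow(x$genes), " genes, ", nrow(x$intervals),
      " coding intervals\n", sep = "")
  print(table(x$genes$category))
  invisible(x)
}

# TRUE for positions (0-based) lying inside any interval of the given panel.
# Strand-independent containment; intervals are half-open.
panel_contains <- function(panel, chrom, pos) {
  iv <- panel$intervals
  vapply(seq_along(chrom), function(i) {
    any(iv$chrom == chrom[i] & iv$start <= pos[i] & pos[i] < iv$end)
  }, logical(1))
}
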