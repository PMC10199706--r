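# On-disk interchange: TSV for tables, FASTA for promoters, BED for peaks
# (0-based half-open), JSON for ground truth.

#' Read and write the pipeline's on-disk formats
#'
#' Counts are TSV with genes as rows (first column `gene`) and sample ids
#' as header; the design is a TSV with the sample sheet columns; peaks are
#' 6-column BED (0-based half-open, name = `tf|gene`); promoters are FASTA
#' with the gene id as record id; ground truth round-trips through JSON.
#'
#' @param counts,design,x,truth,tree Objects to write.
#' @param path File path.
#' @name plastiscan-io
NULL

#' @rdname plastiscan-io
#' @export
write_counts <- function(counts, path) {
  assert_count_matrix(counts)
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(counts$counts)),
                         tibble::as_tibble(counts$counts))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname plastiscan-io
#' @export
read_counts <- function(path, design) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  mode(m) <- "integer"
  rownames(m) <- df$gene
  count_matrix(m, design)
}

#' @rdname plastiscan-io
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname plastiscan-io
#' @export
read_design <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  lv <- lapply(df[design_factors()], unique)
  df |>
    dplyr::mutate(
      cultivar = factor(.data$cultivar, levels = lv$cultivar),
      tissue = factor(.data$tissue, levels = lv$tissue),
      stage = factor(.data$stage, levels = lv$stage, ordered = TRUE),
      soil = factor(.data$soil, levels = lv$soil),
      condition = factor(.data$condition, levels = unique(.data$condition))
    )
}

#' @rdname plastiscan-io
#' @export
write_norm_factors <- function(x, path) {
  readr::write_tsv(tibble::tibble(sample_id = x$sample_id,
                                  norm_factor = x$norm_factor), path)
  invisible(path)
}

#' @rdname plastiscan-io
#' @param promoters Tibble (gene, sequence).
#' @export
write_fasta <- function(promoters, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("package `Biostrings` is required for FASTA IO", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(setNames(promoters$sequence,
                                           promoters$gene))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname plastiscan-io
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("package `Biostrings` is required for FASTA IO", call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  tibble::tibble(gene = names(set),
                 sequence = unname(as.character(set)))
}

#' @rdname plastiscan-io
#' @param peaks Peak tibble (chrom, start, end, tf, gene, score, strand).
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- tibble::tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),   # already 0-based half-open
    end = as.integer(peaks$end),
    name = paste(peaks$tf, peaks$gene, sep = "|"),
    score = peaks$score %||% 0,
    strand = peaks$strand %||% "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname plastiscan-io
#' @export
read_peaks_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    show_col_types = FALSE
  )
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  bed |>
    dplyr::mutate(
      tf = vapply(parts, `[`, character(1), 1),
      gene = vapply(parts, `[`, character(1), 2)
    ) |>
    dplyr::select("chrom", "start", "end", "tf", "gene", "score", "strand")
}

#' @rdname plastiscan-io
#' @export
write_tss <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname plastiscan-io
#' @export
read_tss <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname plastiscan-io
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname plastiscan-io
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tb <- function(x) if (is.null(x) || length(x) == 0) NULL else
    tibble::as_tibble(x)
  new_synthetic_truth(
    genes = as_tb(raw$genes),
    lib_factors = as_tb(raw$lib_factors),
    motifs = as_tb(raw$motifs),
    terms = as_tb(raw$terms),
    seed = raw$seed
  )
}
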