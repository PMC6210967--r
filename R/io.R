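# Readers and writers for the standard formats the pipeline consumes and
# emits. FASTA goes through Biostrings; tabular files through readr with
# explicit column handling (missing cells stay NA, never silent zeros).

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (protein or nucleotide) multi-FASTA file.
#' @param genome_id Genome identifier to attach; defaults to the file stem.
#' @return A tibble with columns `gene_id` (first whitespace-separated token
#'   of the header), `genome_id`, `sequence` and `description` (full header).
#' @export
read_fasta_tbl <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  xs <- Biostrings::readBStringSet(path)
  headers <- names(xs)
  tibble(
    gene_id = sub("\\s.*$", "", headers),
    genome_id = genome_id %||% sub("\\.(fa|fasta|faa|fna|ffn)$", "", basename(path)),
    sequence = unname(as.character(xs)),
    description = headers
  )
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns; headers are written verbatim from
#' `gene_id` (plus ` description` when present and distinct).
#'
#' @param tbl Tibble with columns `gene_id` and `sequence` (optionally
#'   `description`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path) {
  stopifnot(all(c("gene_id", "sequence") %in% names(tbl)))
  headers <- if ("description" %in% names(tbl) &&
                 !all(tbl$description == tbl$gene_id)) {
    tbl$description
  } else {
    tbl$gene_id
  }
  xs <- Biostrings::BStringSet(tbl$sequence)
  names(xs) <- headers
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Read a tab-separated table with a header row
#'
#' Thin wrapper over [readr::read_tsv()] that keeps missing cells as `NA` and
#' never guesses factors.
#'
#' @param path Path to a TSV file.
#' @param col_types Optional readr column specification.
#' @return A tibble.
#' @export
read_tsv_table <- function(path, col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("TSV file not found: %s", path))
  readr::read_tsv(path, col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}

#' Write a table as TSV with a header row
#'
#' @param tbl Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

.blast12 <- c("query_id", "template_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end", "t_start",
              "t_end", "evalue", "bit_score")

#' Read BLAST tabular homology hits
#'
#' Accepts the standard 12-column BLAST tabular layout (`-outfmt 6`), the
#' same layout extended with two trailing coverage columns
#' (`query_coverage_pct`, `template_coverage_pct`), or a native TSV with a
#' header row containing at least `query_id`, `template_id`, `evalue`,
#' `pct_identity` and the two coverage columns.
#'
#' @param path Path to the hits file.
#' @return A tibble with one row per hit; coverage columns are `NA` when the
#'   input does not carry them.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) abort(sprintf("hits file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (grepl("query_id", first, fixed = TRUE)) {
    hits <- read_tsv_table(path)
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           progress = FALSE, show_col_types = FALSE)
    if (ncol(raw) == 12L) {
      names(raw) <- .blast12
      raw$query_coverage_pct <- NA_real_
      raw$template_coverage_pct <- NA_real_
    } else if (ncol(raw) == 14L) {
      names(raw) <- c(.blast12, "query_coverage_pct", "template_coverage_pct")
    } else {
      abort(sprintf("expected 12 or 14 BLAST tabular columns, found %d (%s)",
                    ncol(raw), path))
    }
    hits <- raw
  }
  need <- c("query_id", "template_id", "evalue", "pct_identity")
  missing_cols <- setdiff(need, names(hits))
  if (length(missing_cols)) {
    abort(sprintf("hits table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  as_tibble(hits)
}
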