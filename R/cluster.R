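# Gene-family construction: greedy centroid clustering of protein sequences
# at an identity threshold (the USEARCH-style rule of single-linkage-to-
# centroid, single pass, length-descending order), the family x genome
# presence/count matrix, and the core/accessory/unique partition.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "X")

validate_protein <- function(seqs) {
  bad <- grepl(sprintf("[^%s]", paste(.aa_alphabet, collapse = "")), seqs)
  if (any(bad)) {
    abort(sprintf("protein sequence(s) contain non-standard residues: %s",
                  paste(head(which(bad), 3), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) abort("empty protein sequence")
  invisible(TRUE)
}

blosum62 <- function() {
  if (is.null(.pv_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pv_cache$blosum62 <- e$BLOSUM62
  }
  .pv_cache$blosum62
}

#' Global pairwise protein identity
#'
#' Aligns two protein sequences globally (Needleman-Wunsch with affine gaps,
#' BLOSUM62, gap open 10, gap extension 0.5) and returns the fraction of
#' identical aligned residue pairs over alignment columns, excluding terminal
#' gap columns. `X` residues never count as identical.
#'
#' @param a,b Protein sequences (character strings).
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' pairwise_identity("MKVLA", "MKVLA")
pairwise_identity <- function(a, b) {
  validate_protein(c(a, b))
  sm <- blosum62()
  alpha <- rownames(sm)
  res <- cpp_align_identity(a, b, sm, alpha, gap_open = 10, gap_ext = 0.5)
  res$identity
}

#' Greedy centroid clustering of proteins into gene families
#'
#' Sequences are processed in order of decreasing length (ties broken
#' lexicographically by `gene_id`). Each sequence joins the first existing
#' centroid (in family founding order) whose global identity to it is at
#' least `threshold`; otherwise it founds a new family with itself as
#' centroid. The procedure is deterministic. Centroids are therefore always
#' the longest family members, with lexicographic tie-break.
#'
#' @param proteins Tibble with columns `gene_id`, `genome_id`, `sequence`.
#' @param threshold Identity threshold in `(0, 1]`; default 0.50, the common
#'   within-genus ortholog cut-off.
#' @param prescreen_kmers Minimum number of shared 4-mers a centroid must
#'   have with the query before the full alignment is computed (the
#'   USEARCH-style word screen). Set 0 to disable and align against every
#'   centroid.
#' @return A tibble of class `family_assignment` with columns `gene_id`,
#'   `genome_id`, `family_id`, `centroid_gene_id` and `is_centroid`.
#' @export
greedy_cluster <- function(proteins, threshold = 0.50, prescreen_kmers = 8L) {
  if (!all(c("gene_id", "genome_id", "sequence") %in% names(proteins))) {
    abort("proteins must have columns gene_id, genome_id, sequence")
  }
  if (nrow(proteins) == 0L) abort("no protein sequences supplied")
  if (threshold <= 0 || threshold > 1) abort("threshold must lie in (0, 1]")
  if (anyDuplicated(proteins$gene_id)) abort("gene_id values must be unique")
  validate_protein(proteins$sequence)

  ord <- order(-nchar(proteins$sequence), proteins$gene_id)
  sorted <- proteins[ord, ]
  sm <- blosum62()
  fam_idx <- cpp_greedy_cluster(sorted$sequence, threshold, sm, rownames(sm),
                                gap_open = 10, gap_ext = 0.5,
                                prescreen_kmers = as.integer(prescreen_kmers))
  family_id <- sprintf("FAM%05d", fam_idx)
  centroid_pos <- vapply(split(seq_along(fam_idx), fam_idx), min, integer(1))
  out <- sorted |>
    mutate(family_id = family_id,
           centroid_gene_id = sorted$gene_id[centroid_pos[as.character(fam_idx)]],
           is_centroid = .data$gene_id == .data$centroid_gene_id) |>
    select("gene_id", "genome_id", "family_id", "centroid_gene_id",
           "is_centroid")
  class(out) <- c("family_assignment", class(out))
  out
}

#' Build the family-by-genome pan matrix
#'
#' @param assignment A `family_assignment` (or any tibble with `gene_id`,
#'   `family_id` and, unless `genome_of` is given, `genome_id`).
#' @param genome_of Optional tibble `gene_id` -> `genome_id` overriding the
#'   genome column of `assignment`; every gene must be covered.
#' @param genomes Optional character vector fixing the genome column order
#'   (and admitting genomes with zero genes, which yield all-zero columns).
#' @return A tibble of class `pan_matrix`: `family_id` plus one integer
#'   column per genome holding member counts.
#' @export
build_pan_matrix <- function(assignment, genome_of = NULL, genomes = NULL) {
  tbl <- as_tibble(assignment)
  if (!is.null(genome_of)) {
    tbl <- tbl |>
      select(-dplyr::any_of("genome_id")) |>
      left_join(genome_of, by = "gene_id")
  }
  if (!all(c("gene_id", "genome_id", "family_id") %in% names(tbl))) {
    abort("assignment must provide gene_id, genome_id and family_id")
  }
  if (anyNA(tbl$genome_id)) {
    abort(sprintf("no genome recorded for gene(s): %s",
                  paste(head(tbl$gene_id[is.na(tbl$genome_id)], 3),
                        collapse = ", ")))
  }
  genomes <- genomes %||% sort(unique(tbl$genome_id))
  unknown <- setdiff(unique(tbl$genome_id), genomes)
  if (length(unknown)) {
    abort(sprintf("genome id(s) not in genome list: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  counts <- tbl |>
    count(.data$family_id, .data$genome_id) |>
    tidyr::pivot_wider(names_from = "genome_id", values_from = "n",
                       values_fill = 0L)
  for (g in setdiff(genomes, names(counts))) counts[[g]] <- 0L
  out <- counts |> select("family_id", dplyr::all_of(genomes)) |>
    arrange(.data$family_id)
  class(out) <- c("pan_matrix", class(out))
  out
}

# internal: pan matrix tibble -> integer matrix (families x genomes)
pan_as_matrix <- function(pan) {
  m <- as.matrix(as_tibble(pan)[, -1, drop = FALSE])
  rownames(m) <- pan$family_id
  storage.mode(m) <- "integer"
  m
}

#' Partition the pan-genome into core, accessory and unique families
#'
#' Core families have a nonzero count in every genome, unique families in
#' exactly one, accessory families in two or more but not all. The three
#' classes partition all families.
#'
#' @param pan A `pan_matrix` from [build_pan_matrix()].
#' @return A tibble with columns `family_id`, `n_genomes_present` and
#'   `class` (`"core"`, `"accessory"` or `"unique"`).
#' @export
partition_pan <- function(pan) {
  m <- pan_as_matrix(pan)
  if (ncol(m) < 2L) abort("partition requires at least 2 genomes")
  occ <- rowSums(m > 0L)
  tibble(family_id = rownames(m),
         n_genomes_present = unname(as.integer(occ)),
         class = unname(ifelse(occ == ncol(m), "core",
                               ifelse(occ == 1L, "unique", "accessory"))))
}
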