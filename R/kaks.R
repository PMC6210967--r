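# Nei-Gojobori Ka/Ks: per-codon synonymous/nonsynonymous site counts,
# pathway-averaged difference counts, the Jukes-Cantor-corrected pairwise
# estimator, codon alignments, and the per-family aggregate.

#' Nei-Gojobori synonymous and nonsynonymous site counts per codon
#'
#' For each of the 9 single-nucleotide changes of a codon, the change is
#' classified synonymous or nonsynonymous under the standard code (changes
#' to stop codons count as nonsynonymous), giving `s` = sum over positions
#' of the synonymous fraction and `n = 3 - s`.
#'
#' @param codons Character vector of sense codons.
#' @return A tibble with columns `codon`, `s`, `n`; codons containing
#'   ambiguous bases yield `NA` rows (a skip signal).
#' @export
#' @examples
#' ng_site_counts(c("TTT", "ATG"))
ng_site_counts <- function(codons) {
  tb <- codon_tables()
  if (any(codons %in% tb$stops)) {
    abort("stop codons have no site counts")
  }
  idx <- match(codons, tb$sense)
  if (anyNA(idx)) {
    abort("ambiguous or invalid codon(s): not sense codons of the standard code")
  }
  tibble(codon = codons,
         s = unname(tb$sites[idx, "s"]),
         n = unname(tb$sites[idx, "n"]))
}

#' Nei-Gojobori pathway-averaged difference counts between two codons
#'
#' Averages synonymous/nonsynonymous step counts over all minimal
#' mutational pathways between the codons, excluding pathways passing
#' through stop codons; when every pathway is blocked, the stop-inclusive
#' pathway set is used instead (flagged in `blocked`). By construction
#' `s_d + n_d` equals the nucleotide Hamming distance of the codons.
#'
#' @param a,b Sense codons (character scalars or equal-length vectors,
#'   compared elementwise).
#' @return A tibble with columns `s_d`, `n_d`, `blocked`.
#' @export
#' @examples
#' ng_differences("TTT", "GTA")
ng_differences <- function(a, b) {
  tb <- codon_tables()
  ia <- match(a, tb$sense)
  ib <- match(b, tb$sense)
  if (anyNA(ia) || anyNA(ib)) abort("inputs must be unambiguous sense codons")
  tibble(s_d = tb$sd[cbind(ia, ib)],
         n_d = tb$nd[cbind(ia, ib)],
         blocked = tb$blocked[cbind(ia, ib)])
}

#' Pairwise Ka/Ks by the Nei-Gojobori method
#'
#' Counts synonymous/nonsynonymous sites (`S`, `N`, averaged over the two
#' sequences) and pathway-averaged differences (`s_d`, `n_d`) over the
#' gap-free aligned codon columns, forms the proportions `p_s = s_d/S`,
#' `p_n = n_d/N`, and applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)` to each. `omega = Ka/Ks` is flagged
#' `undefined_omega` when `Ks = 0` and the record is flagged `saturated`
#' when either proportion reaches the correction's 3/4 ceiling.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length (codon gaps
#'   `"---"` allowed; any column with a gap in either sequence is excluded).
#' @return A one-row tibble: `S`, `N`, `s_d`, `n_d`, `p_s`, `p_n`, `Ka`,
#'   `Ks`, `omega`, `flag` (`"ok"`, `"undefined_omega"` or `"saturated"`),
#'   `n_codons` (compared columns).
#' @export
ng_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    abort("aligned sequences must have equal length")
  }
  ca <- split_codons(cds_a, "sequence a")
  cb <- split_codons(cds_b, "sequence b")
  gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!gap]; cb <- cb[!gap]
  tb <- codon_tables()
  ok <- ca %in% tb$sense & cb %in% tb$sense
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) abort("no comparable gap-free sense-codon columns")

  ia <- match(ca, tb$sense); ib <- match(cb, tb$sense)
  S <- (sum(tb$sites[ia, "s"]) + sum(tb$sites[ib, "s"])) / 2
  N <- (sum(tb$sites[ia, "n"]) + sum(tb$sites[ib, "n"])) / 2
  s_d <- sum(tb$sd[cbind(ia, ib)])
  n_d <- sum(tb$nd[cbind(ia, ib)])
  p_s <- s_d / S
  p_n <- n_d / N
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(p_s)
  Ka <- jc(p_n)
  flag <- if (is.na(Ka) || is.na(Ks)) "saturated"
          else if (Ks == 0) "undefined_omega" else "ok"
  omega <- if (flag == "ok") Ka / Ks else NA_real_
  out <- tibble(S = S, N = N, s_d = s_d, n_d = n_d, p_s = p_s, p_n = p_n,
                Ka = Ka, Ks = Ks, omega = omega, flag = flag,
                n_codons = length(ca))
  class(out) <- c("kaks_record", class(out))
  out
}

# find mafft (optional system dependency for length-variable families)
mafft_path <- function() {
  p <- Sys.which("mafft")
  if (!nzchar(p)) abort("mafft not found on PATH; needed to align length-variable families")
  p
}

#' Codon alignment of a gene family
#'
#' Translates the coding sequences, aligns the proteins globally, and
#' back-translates the protein alignment to codons. Families whose proteins
#' all have equal length are aligned positionally (no gaps); otherwise the
#' proteins are aligned with MAFFT. Sequences with internal stop codons are
#' dropped with a message. Downstream Nei-Gojobori counting excludes any
#' column with a gap in any sequence.
#'
#' @param family_cds Tibble with columns `gene_id` and `cds`, or a named
#'   character vector of CDS.
#' @return A tibble with columns `gene_id` and `aligned_cds` (equal-length
#'   codon-gapped sequences).
#' @export
codon_align <- function(family_cds) {
  if (!is.data.frame(family_cds)) {
    family_cds <- tibble(gene_id = names(family_cds) %||%
                           paste0("seq", seq_along(family_cds)),
                         cds = unname(family_cds))
  }
  prot <- translate_cds(setNames(family_cds$cds, family_cds$gene_id))
  internal_stop <- grepl("*", prot, fixed = TRUE)
  if (any(internal_stop)) {
    inform(sprintf("dropping %d sequence(s) with internal stop codons: %s",
                   sum(internal_stop),
                   paste(head(family_cds$gene_id[internal_stop], 3),
                         collapse = ", ")))
    family_cds <- family_cds[!internal_stop, ]
    prot <- prot[!internal_stop]
  }
  if (nrow(family_cds) == 0L) abort("no translatable sequences in family")

  if (length(unique(nchar(prot))) == 1L) {
    aligned_prot <- prot
  } else {
    fa_in <- tempfile(fileext = ".faa")
    on.exit(unlink(fa_in), add = TRUE)
    write_fasta(tibble(gene_id = family_cds$gene_id, sequence = prot), fa_in)
    out <- suppressWarnings(
      system2(mafft_path(), c("--auto", "--quiet", "--amino", fa_in),
              stdout = TRUE, stderr = FALSE))
    aln <- read_fasta_tbl(textConnection_fasta(out))
    aligned_prot <- toupper(setNames(aln$sequence, aln$gene_id)[family_cds$gene_id])
  }
  aligned_cds <- vapply(seq_len(nrow(family_cds)), function(i) {
    cods <- split_codons(family_cds$cds[i], family_cds$gene_id[i])
    aa <- strsplit(aligned_prot[i], "")[[1]]
    out <- character(length(aa))
    k <- 0L
    for (j in seq_along(aa)) {
      if (aa[j] == "-") out[j] <- "---"
      else { k <- k + 1L; out[j] <- cods[k] }
    }
    paste(out, collapse = "")
  }, character(1))
  tibble(gene_id = family_cds$gene_id, aligned_cds = aligned_cds)
}

# helper: materialize in-memory FASTA lines to a temp file and return path
textConnection_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

#' Family-level aggregate Ka/Ks
#'
#' Computes all pairwise [ng_kaks()] records on a codon alignment and
#' aggregates: family `Ka` and `Ks` are the means over pairs with defined,
#' unsaturated estimates; family `omega` is their ratio. Pairs excluded
#' from the aggregate (saturated or `Ks = 0`) are counted, never silently
#' dropped.
#'
#' @param alignment Tibble from [codon_align()] (columns `gene_id`,
#'   `aligned_cds`).
#' @return A one-row tibble: `n_seq`, `n_pairs`, `n_excluded`, `Ka`, `Ks`,
#'   `omega`, `flag` (`"ok"` or `"no_valid_pair"`), plus a `pairs`
#'   list-column with the per-pair records.
#' @export
family_omega <- function(alignment) {
  stopifnot(all(c("gene_id", "aligned_cds") %in% names(alignment)))
  n <- nrow(alignment)
  if (n < 2L) abort("family must contain at least 2 sequences")
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      rec <- ng_kaks(alignment$aligned_cds[i], alignment$aligned_cds[j])
      rec$gene_a <- alignment$gene_id[i]
      rec$gene_b <- alignment$gene_id[j]
      pairs[[length(pairs) + 1L]] <- rec
    }
  }
  pairs <- bind_rows(pairs)
  valid <- pairs$flag == "ok"
  if (!any(valid)) {
    return(tibble(n_seq = n, n_pairs = nrow(pairs),
                  n_excluded = nrow(pairs), Ka = NA_real_, Ks = NA_real_,
                  omega = NA_real_, flag = "no_valid_pair",
                  pairs = list(pairs)))
  }
  Ka <- mean(pairs$Ka[valid])
  Ks <- mean(pairs$Ks[valid])
  tibble(n_seq = n, n_pairs = nrow(pairs), n_excluded = sum(!valid),
         Ka = Ka, Ks = Ks, omega = Ka / Ks, flag = "ok",
         pairs = list(pairs))
}

#' Ka/Ks for every core family of a clustered dataset
#'
#' Convenience wrapper running [codon_align()] and [family_omega()] over
#' each family of a given class.
#'
#' @param genes Tibble with columns `gene_id`, `family_id`, `cds`.
#' @param families Character vector of family ids to process (e.g. the core
#'   set from [partition_pan()]).
#' @return A tibble with one row per processed family (`family_id` plus the
#'   [family_omega()] columns); families with fewer than 2 members are
#'   skipped.
#' @export
core_kaks <- function(genes, families) {
  stopifnot(all(c("gene_id", "family_id", "cds") %in% names(genes)))
  out <- list()
  for (f in families) {
    sub <- genes[genes$family_id == f, c("gene_id", "cds")]
    if (nrow(sub) < 2L) next
    rec <- family_omega(codon_align(sub))
    rec$family_id <- f
    out[[length(out) + 1L]] <- rec
  }
  bind_rows(out) |> select("family_id", dplyr::everything())
}

#' Ka versus Ks scatter of per-family estimates
#'
#' @param object A tibble of per-family records from [core_kaks()].
#' @param ... Unused.
#' @return A ggplot object with the Ka = Ks diagonal for reference.
#' @export
plot_kaks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$Ks, y = .data$Ka)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(shape = 3) +
    ggplot2::labs(x = expression(K[s]), y = expression(K[a])) +
    ggplot2::theme_minimal()
}
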