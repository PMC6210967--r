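# Codon-usage relative entropy: observed codon frequencies, two explicit
# null models for the expected frequencies, Kullback-Leibler divergence in
# bits, and the Welch comparison of core-gene versus whole-chromosome
# entropies.

#' Observed sense-codon counts of a coding-sequence set
#'
#' Tallies the 61 sense codons of the standard code across a set of CDS.
#' Codons containing ambiguous bases are skipped; stop codons are never
#' counted.
#'
#' @param cds Character vector of coding sequences (each length a multiple
#'   of 3), optionally named by gene id; or a data frame with columns
#'   `gene_id` and `cds`.
#' @param label Optional gene-set label (e.g. `"core"`, `"chromosome"`).
#' @return A tibble of class `codon_counts` with columns `codon`, `aa`,
#'   `count`; the total codon count is in attribute `total`, the label in
#'   attribute `label`.
#' @export
#' @examples
#' observed_codon_frequencies("ATGAAATAA")
observed_codon_frequencies <- function(cds, label = NULL) {
  if (is.data.frame(cds)) {
    cds <- setNames(cds$cds, cds$gene_id)
  }
  tb <- codon_tables()
  counts <- setNames(numeric(length(tb$sense)), tb$sense)
  skipped_ambiguous <- 0L
  for (i in seq_along(cds)) {
    what <- names(cds)[i] %||% paste0("record ", i)
    cods <- split_codons(cds[[i]], what = what)
    known <- cods %in% tb$codons
    skipped_ambiguous <- skipped_ambiguous + sum(!known)
    cods <- cods[known & !(cods %in% tb$stops)]
    if (length(cods)) {
      t0 <- table(factor(cods, levels = tb$sense))
      counts <- counts + as.numeric(t0)
    }
  }
  if (sum(counts) == 0) abort("no usable sense codons in the input set")
  out <- tibble(codon = tb$sense, aa = unname(tb$aa[tb$sense]),
                count = as.numeric(counts))
  attr(out, "total") <- sum(counts)
  attr(out, "label") <- label
  attr(out, "skipped_ambiguous") <- skipped_ambiguous
  class(out) <- c("codon_counts", class(out))
  out
}

#' Expected sense-codon frequencies under an explicit null model
#'
#' Two null constructions are offered. `positional_nucleotide` (default):
#' the expected frequency of codon `xyz` is the product of the
#' position-specific nucleotide frequencies `f1(x) f2(y) f3(z)` estimated
#' from the same gene set, renormalized over the 61 sense codons — i.e. the
#' codon usage expected if the three codon positions were independent.
#' `uniform_synonymous`: each codon's expectation is its amino acid's
#' observed frequency divided equally among that amino acid's synonymous
#' codons — the no-codon-preference null.
#'
#' @param cds Coding sequences, as in [observed_codon_frequencies()], or an
#'   existing `codon_counts` object.
#' @param null_model `"positional_nucleotide"` or `"uniform_synonymous"`.
#' @param pseudocount Added to every expected frequency cell only when some
#'   codon with nonzero observed count would otherwise have zero
#'   expectation (the fallback is reported via a message).
#' @return A named numeric vector over the 61 sense codons, summing to 1.
#' @export
expected_codon_frequencies <- function(cds,
                                       null_model = c("positional_nucleotide",
                                                      "uniform_synonymous"),
                                       pseudocount = 0.5) {
  null_model <- match.arg(null_model)
  obs <- if (inherits(cds, "codon_counts")) cds else
    observed_codon_frequencies(cds)
  tb <- codon_tables()
  counts <- setNames(obs$count, obs$codon)[tb$sense]
  if (sum(counts) == 0) abort("empty codon counts")

  if (null_model == "positional_nucleotide") {
    f <- matrix(0, nrow = 4, ncol = 3, dimnames = list(.pv_bases, NULL))
    for (pos in 1:3) {
      nt <- substr(tb$sense, pos, pos)
      f[, pos] <- vapply(.pv_bases,
                         function(b) sum(counts[nt == b]), numeric(1))
      f[, pos] <- f[, pos] / sum(f[, pos])
    }
    q <- vapply(tb$sense, function(cod) {
      f[substr(cod, 1, 1), 1] * f[substr(cod, 2, 2), 2] *
        f[substr(cod, 3, 3), 3]
    }, numeric(1))
  } else {
    aa <- tb$aa[tb$sense]
    aa_freq <- tapply(counts, aa, sum) / sum(counts)
    fam_size <- table(aa)
    q <- as.numeric(aa_freq[aa] / fam_size[aa])
    names(q) <- tb$sense
  }
  q <- q / sum(q)
  if (any(q == 0 & counts > 0)) {
    inform("zero expected frequency with nonzero observed count: applying pseudocount fallback")
    q <- q + pseudocount / sum(counts)
    q <- q / sum(q)
  }
  q
}

#' Kullback-Leibler divergence of observed from expected codon usage
#'
#' `DKL = sum_c p_obs(c) * log2(p_obs(c) / p_exp(c))` over the 61 sense
#' codons, in bits. Codons with zero observed count contribute 0. By Gibbs'
#' inequality the result is nonnegative, and 0 exactly when observed equals
#' expected.
#'
#' @param observed A `codon_counts` object (or a named count/frequency
#'   vector over sense codons).
#' @param expected Named expected-frequency vector from
#'   [expected_codon_frequencies()].
#' @return DKL in bits (nonnegative scalar).
#' @export
relative_entropy <- function(observed, expected) {
  tb <- codon_tables()
  counts <- if (inherits(observed, "codon_counts") || is.data.frame(observed)) {
    setNames(observed$count, observed$codon)[tb$sense]
  } else {
    observed[tb$sense]
  }
  p <- counts / sum(counts)
  q <- expected[tb$sense]
  q <- q / sum(q)
  pos <- which(p > 0)
  if (any(q[pos] <= 0)) {
    abort("expected frequency is zero where observed count is positive")
  }
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Per-genome relative entropy of a gene subset versus the chromosome
#'
#' For every genome, computes the codon-usage DKL of a designated gene
#' subset (by default the core families) and of the whole chromosome (all
#' genes of that genome), each against the expected frequencies estimated
#' from the same gene set under `null_model`.
#'
#' @param genes Tibble with columns `genome_id`, `cds` and a logical or
#'   class column selecting the subset (see `subset_col`).
#' @param subset_col Column name defining the subset; either logical, or
#'   character where values equal to `subset_value` select the subset.
#' @param subset_value Value of `subset_col` marking subset membership
#'   (default `"core"`).
#' @param null_model Passed to [expected_codon_frequencies()].
#' @return A tibble with columns `genome_id`, `dkl_subset`,
#'   `dkl_chromosome` (bits).
#' @export
genome_relative_entropy <- function(genes, subset_col = "class",
                                    subset_value = "core",
                                    null_model = "positional_nucleotide") {
  stopifnot(all(c("genome_id", "cds", subset_col) %in% names(genes)))
  sel <- genes[[subset_col]]
  genes$.in_subset <- if (is.logical(sel)) sel else sel == subset_value
  dkl_of <- function(cds, label) {
    if (length(cds) == 0) return(NA_real_)
    o <- observed_codon_frequencies(cds, label = label)
    relative_entropy(o, expected_codon_frequencies(o, null_model))
  }
  purrr::map_dfr(split(genes, genes$genome_id), function(g) {
    tibble(genome_id = g$genome_id[1],
           dkl_subset = dkl_of(g$cds[g$.in_subset], "subset"),
           dkl_chromosome = dkl_of(g$cds, "chromosome"))
  })
}

#' Welch comparison of core versus chromosome relative entropies
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, comparing per-genome DKL values of a gene subset (core) against
#' per-genome chromosome DKL values. Reports the two-sided p-value and the
#' one-sided p-value for the subset being higher.
#'
#' @param core_dkls,chrom_dkls Numeric vectors of per-genome DKL values
#'   (each length >= 2). Alternatively, `core_dkls` may be the tibble
#'   returned by [genome_relative_entropy()], in which case `chrom_dkls` is
#'   ignored.
#' @return A one-row tibble: `mean_core`, `mean_chromosome`, `welch_t`,
#'   `welch_df`, `p_two_sided`, `p_core_greater`.
#' @export
compare_core_vs_chromosome <- function(core_dkls, chrom_dkls = NULL) {
  if (is.data.frame(core_dkls)) {
    chrom_dkls <- core_dkls$dkl_chromosome
    core_dkls <- core_dkls$dkl_subset
  }
  x <- core_dkls[!is.na(core_dkls)]
  y <- chrom_dkls[!is.na(chrom_dkls)]
  if (length(x) < 2 || length(y) < 2) abort("both groups need >= 2 values")
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  if (vx + vy == 0) {
    t_stat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    df <- length(x) + length(y) - 2
  } else {
    t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  }
  p_two <- if (is.infinite(t_stat)) 0 else 2 * pt(-abs(t_stat), df)
  p_greater <- if (is.infinite(t_stat)) {
    if (t_stat > 0) 0 else 1
  } else {
    pt(t_stat, df, lower.tail = FALSE)
  }
  if (t_stat == 0 && vx + vy == 0) { p_two <- 1; p_greater <- 1 }
  tibble(mean_core = mean(x), mean_chromosome = mean(y),
         welch_t = t_stat, welch_df = df,
         p_two_sided = min(p_two, 1), p_core_greater = p_greater)
}
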