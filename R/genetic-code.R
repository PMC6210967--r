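# Standard-genetic-code machinery shared by the simulator, codon-usage and
# Ka/Ks code. All tables are computed once per session and cached; the code
# table itself comes from Biostrings::GENETIC_CODE so there is a single
# authority for codon -> amino-acid mapping.

.pv_cache <- new.env(parent = emptyenv())

.pv_bases <- c("T", "C", "A", "G")

#' Codon tables for the standard genetic code
#'
#' Returns the cached table set used throughout the package: the 64 codons,
#' their amino-acid translations, the 61 sense codons, per-codon synonymous /
#' nonsynonymous site counts (Nei-Gojobori convention: mutations to stop
#' codons count as nonsynonymous, so s + n = 3 for every codon), and the
#' 61 x 61 pathway-averaged synonymous/nonsynonymous difference tables.
#'
#' @return A list with elements `codons`, `aa` (named by codon), `sense`,
#'   `stops`, `sites` (matrix, rows = sense codons, columns `s`, `n`),
#'   `sd`/`nd` (61 x 61 matrices) and `blocked` (logical 61 x 61, pairs whose
#'   every minimal pathway passes through a stop codon, counted with the
#'   stop-inclusive fallback).
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.pv_cache$tables)) return(.pv_cache$tables)
  codons <- as.vector(outer(outer(.pv_bases, .pv_bases, paste0), .pv_bases, paste0))
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  names(aa) <- codons
  sense <- codons[aa != "*"]
  stops <- codons[aa == "*"]

  sites <- t(vapply(sense, function(cod) {
    s <- 0
    for (pos in 1:3) {
      nt <- substr(cod, pos, pos)
      for (alt in setdiff(.pv_bases, nt)) {
        mut <- cod
        substr(mut, pos, pos) <- alt
        if (aa[[mut]] != "*" && aa[[mut]] == aa[[cod]]) s <- s + 1 / 3
      }
    }
    c(s = s, n = 3 - s)
  }, c(s = 0, n = 0)))

  nsense <- length(sense)
  sd_m <- matrix(0, nsense, nsense, dimnames = list(sense, sense))
  nd_m <- sd_m
  blocked <- matrix(FALSE, nsense, nsense, dimnames = list(sense, sense))
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in seq_len(nsense)) {
    for (j in seq_len(nsense)) {
      if (i == j) next
      a <- sense[i]; b <- sense[j]
      pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      k <- length(pos)
      orders <- switch(k,
        list(pos),
        list(pos, rev(pos)),
        lapply(perms3, function(p) pos[p]))
      paths <- list(); paths_any <- list()
      for (ord in orders) {
        cur <- a; s_d <- 0; n_d <- 0; via_stop <- FALSE
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(b, p, p)
          if (aa[[nxt]] == "*") via_stop <- TRUE
          if (aa[[nxt]] != "*" && aa[[cur]] != "*" && aa[[nxt]] == aa[[cur]]) {
            s_d <- s_d + 1
          } else {
            n_d <- n_d + 1
          }
          cur <- nxt
        }
        paths_any[[length(paths_any) + 1L]] <- c(s_d, n_d)
        if (!via_stop) paths[[length(paths) + 1L]] <- c(s_d, n_d)
      }
      if (length(paths) == 0L) {
        # every minimal pathway is blocked by a stop codon: fall back to
        # counting all pathways (stop-passing steps scored nonsynonymous)
        paths <- paths_any
        blocked[i, j] <- TRUE
      }
      avg <- colMeans(do.call(rbind, paths))
      sd_m[i, j] <- avg[1]
      nd_m[i, j] <- avg[2]
    }
  }
  # single-nucleotide neighbor tables for the substitution sampler:
  # neigh[c, k] = 0-based sense index of the codon reached from sense codon c
  # by proposal k (position 1..3 x alternative base 1..3), or -1 for a stop;
  # syn flags synonymous proposals
  neigh <- matrix(-1L, nsense, 9L)
  syn <- matrix(0L, nsense, 9L)
  sense_index <- setNames(seq_len(nsense) - 1L, sense)
  for (i in seq_len(nsense)) {
    cod <- sense[i]
    k <- 0L
    for (pos in 1:3) {
      nt <- substr(cod, pos, pos)
      for (alt in setdiff(.pv_bases, nt)) {
        k <- k + 1L
        mut <- cod
        substr(mut, pos, pos) <- alt
        if (aa[[mut]] != "*") {
          neigh[i, k] <- sense_index[[mut]]
          if (aa[[mut]] == aa[[cod]]) syn[i, k] <- 1L
        }
      }
    }
  }
  # preferred codon per amino acid (lexicographically first), the anchor of
  # the generator's codon-usage bias
  pref <- rep(FALSE, nsense)
  for (a in unique(aa[sense])) {
    fam <- sense[aa[sense] == a]
    pref[sense == sort(fam)[1]] <- TRUE
  }
  .pv_cache$tables <- list(codons = codons, aa = aa, sense = sense,
                           stops = stops, sites = sites,
                           sd = sd_m, nd = nd_m, blocked = blocked,
                           neigh = neigh, syn = syn, preferred = pref)
  .pv_cache$tables
}

# evaluate `code` under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# split a CDS string into codons; error (naming `what`) if length is not a
# multiple of 3
split_codons <- function(seq, what = "sequence") {
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    abort(sprintf("CDS length of %s is %d, not a multiple of 3", what, n))
  }
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# translate a vector of codons to a protein string (standard code); ambiguous
# codons become X
translate_codons <- function(codons) {
  tb <- codon_tables()
  aa <- tb$aa[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate coding sequences with the standard genetic code
#'
#' @param cds Character vector of nucleotide coding sequences (each a multiple
#'   of 3 long).
#' @return Character vector of amino-acid sequences (terminal stop, if any,
#'   is dropped; internal stops are translated as `*`).
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(cds) {
  vapply(seq_along(cds), function(i) {
    cods <- split_codons(cds[[i]], what = names(cds)[i] %||% paste0("record ", i))
    aa <- strsplit(translate_codons(cods), "")[[1]]
    if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1))
}
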