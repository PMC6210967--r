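# Independent oracles and fixture builders. Every oracle here is a
# straight-line reimplementation kept deliberately separate from the package
# code paths it checks.

ORACLE_BASES <- c("T", "C", "A", "G")
ORACLE_GC <- Biostrings::GENETIC_CODE

oracle_sense_codons <- function() {
  cods <- as.vector(outer(outer(ORACLE_BASES, ORACLE_BASES, paste0),
                          ORACLE_BASES, paste0))
  cods[ORACLE_GC[cods] != "*"]
}

# site counts by direct enumeration of the 9 single-nucleotide mutations
oracle_site_counts <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (ORACLE_GC[[mut]] != "*" && ORACLE_GC[[mut]] == ORACLE_GC[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged difference counts by recursive enumeration of orderings
oracle_ng_differences <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(s_d = 0, n_d = 0))
  walk <- function(cur, remaining) {
    # returns list of c(s, n, blocked) over orderings of remaining positions
    if (length(remaining) == 0) return(list(c(0, 0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      step_stop <- ORACLE_GC[[nxt]] == "*"
      syn <- !step_stop && ORACLE_GC[[nxt]] == ORACLE_GC[[cur]]
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- c(tail[1] + as.numeric(syn),
                                    tail[2] + as.numeric(!syn),
                                    max(tail[3], as.numeric(step_stop)))
      }
    }
    out
  }
  paths <- do.call(rbind, walk(a, pos))
  ok <- paths[, 3] == 0
  use <- if (any(ok)) paths[ok, , drop = FALSE] else paths
  c(s_d = mean(use[, 1]), n_d = mean(use[, 2]))
}

# column-by-column Nei-Gojobori Ka/Ks using only the oracles above
oracle_ng_kaks <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a) - 2, 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b) - 2, 3), seq(3, nchar(cds_b), 3))
  Sa <- sum(vapply(ca, function(c) oracle_site_counts(c)["s"], 1))
  Sb <- sum(vapply(cb, function(c) oracle_site_counts(c)["s"], 1))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca),
                      function(i) oracle_ng_differences(ca[i], cb[i]),
                      c(s_d = 0, n_d = 0)))
  ps <- d[1] / S; pn <- d[2] / N
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, s_d = unname(d[1]), n_d = unname(d[2]),
       Ks = jc(ps), Ka = jc(pn))
}

# naive quadratic greedy clustering: same rule, plain R loop
oracle_greedy <- function(proteins, threshold) {
  ord <- order(-nchar(proteins$sequence), proteins$gene_id)
  sorted <- proteins[ord, ]
  centroids <- integer(0)
  fam <- integer(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    hit <- 0L
    for (c in seq_along(centroids)) {
      if (pairwise_identity(sorted$sequence[i],
                            sorted$sequence[centroids[c]]) >= threshold) {
        hit <- c
        break
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      hit <- length(centroids)
    }
    fam[i] <- hit
  }
  tibble::tibble(gene_id = sorted$gene_id, family = fam)
}

# brute-force pan/core curves recomputed from an explicit genome ordering
oracle_curves <- function(presence, ordering) {
  N <- length(ordering)
  pan <- integer(N); core <- integer(N)
  for (n in seq_len(N)) {
    sub <- presence[, ordering[seq_len(n)], drop = FALSE] > 0
    pan[n] <- sum(rowSums(sub) > 0)
    core[n] <- sum(rowSums(sub) == n)
  }
  list(pan = pan, core = core)
}

random_protein <- function(n, alphabet = setdiff(c("A", "R", "N", "D", "C",
  "Q", "E", "G", "H", "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y",
  "V"), NULL)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  paste(sample(oracle_sense_codons(), n_codons, replace = TRUE),
        collapse = "")
}

# point-mutate a protein at k positions, guaranteeing a different residue
mutate_protein <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  for (p in pos) chars[p] <- sample(setdiff(aas, chars[p]), 1)
  paste(chars, collapse = "")
}

# random pan-matrix tibble for property tests
random_pan_matrix <- function(n_fam, n_genomes, p = 0.4) {
  m <- matrix(rbinom(n_fam * n_genomes, 2, p), n_fam, n_genomes)
  m[rowSums(m) == 0, 1] <- 1L  # every family occurs somewhere
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- sprintf("G%02d", seq_len(n_genomes))
  out <- dplyr::bind_cols(tibble::tibble(family_id = sprintf("F%04d", seq_len(n_fam))), out)
  class(out) <- c("pan_matrix", class(out))
  out
}
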