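# Feature-abundance statistics: COG-class abundance matrices, Spearman
# correlation with genome size (exact permutation p below n = 10,
# t-approximation above), Kruskal-Wallis group differences, and the
# conserved-peptide proteome scan.

.cog_classes <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                  "L", "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V",
                  "W", "Y", "Z")

#' Per-genome COG-class abundance matrix
#'
#' Counts genes per genome per functional class. A gene assigned to more
#' than one class is counted once under `MC` ("multiple classes") and not
#' under its individual classes. The `R` ("general function prediction
#' only"), `S` ("function unknown") and `MC` columns are produced but
#' flagged for exclusion from genome-size correlation analyses.
#'
#' @param assignments Tibble with columns `gene_id`, `genome_id`, `classes`
#'   (a string of one-letter COG classes, e.g. `"G"` or `"GK"`, separators
#'   `,;/ ` allowed; empty/`NA` means unassigned and is not counted).
#' @return A wide tibble, one row per genome: `genome_id` plus one count
#'   column per observed class and `MC`; attribute
#'   `excluded_from_correlation` lists `R`, `S`, `MC`.
#' @export
cog_abundance_matrix <- function(assignments) {
  stopifnot(all(c("gene_id", "genome_id", "classes") %in% names(assignments)))
  cls_list <- strsplit(gsub("[,;/ ]+", "", assignments$classes %||% ""), "")
  cls_list[is.na(assignments$classes)] <- list(character(0))
  cls_list <- lapply(cls_list, unique)
  bad <- which(vapply(cls_list,
                      function(x) any(!x %in% .cog_classes), logical(1)))
  if (length(bad)) {
    abort(sprintf("unknown COG class letter in row(s): %s (gene %s)",
                  paste(head(bad, 3), collapse = ", "),
                  assignments$gene_id[bad[1]]))
  }
  eff <- vapply(cls_list, function(x) {
    if (length(x) == 0L) NA_character_
    else if (length(x) > 1L) "MC" else x
  }, character(1))
  tbl <- tibble(genome_id = assignments$genome_id, class = eff) |>
    filter(!is.na(.data$class)) |>
    count(.data$genome_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  cols <- intersect(c(.cog_classes, "MC"), names(tbl))
  out <- tbl |> select("genome_id", dplyr::all_of(cols))
  attr(out, "excluded_from_correlation") <- c("R", "S", "MC")
  out
}

# all permutations of 1..n (n <= 9), rows = permutations
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with a split p-value scheme
#'
#' `rho` is the Pearson correlation of average ranks. For `n >= 10` the
#' p-value uses the t-approximation with `n - 2` degrees of freedom; for
#' `n < 10` it is the exact (full enumeration) permutation p-value,
#' two-sided on `|rho|`.
#'
#' @param x,y Numeric vectors of equal length `>= 4`.
#' @return A one-row tibble: `rho`, `p_value`, `method`, `n`, `flag`
#'   (`"ok"` or `"constant_input"`, in which case `rho` is `NA`).
#' @export
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5))
spearman <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) abort("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(tibble(rho = NA_real_, p_value = NA_real_,
                  method = NA_character_, n = n, flag = "constant_input"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t_approximation"
  } else {
    perms <- all_perms(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    stats_all <- as.vector(matrix(ry_c[perms], nrow(perms)) %*% rx_c) / denom
    p <- mean(abs(stats_all) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  }
  tibble(rho = rho, p_value = min(p, 1), method = method, n = n, flag = "ok")
}

#' Correlate feature abundances with genome size
#'
#' Computes [spearman()] of every retained numeric feature column against
#' `genome_size_bp`. Columns named `R`, `S` and `MC` (poorly characterized
#' and multi-class COG bins) are excluded by convention.
#'
#' @param table Feature table: one row per genome, a `genome_size_bp`
#'   column, and numeric feature columns.
#' @param alpha Significance level for the `significant` flag (default
#'   0.001).
#' @param exclude Additional columns to skip.
#' @return A tibble (`feature`, `rho`, `p_value`, `method`, `n`,
#'   `significant`), sorted by decreasing `rho`.
#' @export
correlate_with_genome_size <- function(table, alpha = 0.001,
                                       exclude = character(0)) {
  if (!"genome_size_bp" %in% names(table)) {
    abort("table must contain a genome_size_bp column")
  }
  skip <- c("genome_id", "genome_size_bp", "R", "S", "MC", exclude)
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], skip)
  out <- purrr::map_dfr(feats, function(f) {
    res <- spearman(table$genome_size_bp, table[[f]])
    res$feature <- f
    res
  })
  out |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha) |>
    select("feature", "rho", "p_value", "method", "n", "significant") |>
    arrange(desc(.data$rho))
}

#' Kruskal-Wallis rank test across multiple groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `k - 1` degrees
#' of freedom (delegates to [stats::kruskal.test()]); the degenerate case
#' of all values identical yields `H = 0`, `p = 1`.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return A one-row tibble: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    abort("need >= 2 groups with >= 2 values each")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(tibble(H = 0, df = length(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, g)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Scan proteomes for a conserved peptide and its near variants
#'
#' Slides the query peptide over every protein at every offset and reports
#' exact substring hits and variant hits differing at up to `max_mismatch`
#' positions (variant hits are never also exact hits).
#'
#' @param proteome Tibble with columns `gene_id`, `genome_id`, `sequence`.
#' @param peptide Query peptide (default the SecA-encrypted
#'   immunomodulatory peptide `"FAIVDEVDSILIDEAR"`).
#' @param max_mismatch Maximum mismatches for a variant hit (default 1).
#' @return A tibble of hits: `genome_id`, `gene_id`, `position` (1-based
#'   offset), `type` (`"exact"`/`"variant"`), `n_mismatch`, `mismatches`
#'   (e.g. `"F1Y"`: query residue, position in peptide, found residue).
#' @export
peptide_scan <- function(proteome, peptide = "FAIVDEVDSILIDEAR",
                         max_mismatch = 1L) {
  stopifnot(all(c("gene_id", "genome_id", "sequence") %in% names(proteome)))
  if (nchar(peptide) < 1L) abort("peptide must be non-empty")
  k <- nchar(peptide)
  pep <- strsplit(peptide, "")[[1]]
  hits <- list()
  for (i in seq_len(nrow(proteome))) {
    s <- proteome$sequence[i]
    L <- nchar(s)
    if (L < k) next
    chars <- strsplit(s, "")[[1]]
    for (off in seq_len(L - k + 1L)) {
      win <- chars[off:(off + k - 1L)]
      mm <- which(win != pep)
      if (length(mm) > max_mismatch) next
      hits[[length(hits) + 1L]] <- tibble(
        genome_id = proteome$genome_id[i],
        gene_id = proteome$gene_id[i],
        position = off,
        type = if (length(mm) == 0L) "exact" else "variant",
        n_mismatch = length(mm),
        mismatches = if (length(mm) == 0L) NA_character_ else
          paste(sprintf("%s%d%s", pep[mm], mm, win[mm]), collapse = ","))
    }
  }
  if (!length(hits)) {
    return(tibble(genome_id = character(0), gene_id = character(0),
                  position = integer(0), type = character(0),
                  n_mismatch = integer(0), mismatches = character(0)))
  }
  bind_rows(hits)
}
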