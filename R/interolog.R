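# Interolog transfer of host-microbe protein-protein interactions: homology
# hit filtering, edge prediction with joint worst-of-pair metrics, and
# network summaries.

#' Filter homology hits by the four interolog thresholds
#'
#' A hit survives iff `evalue <= evalue_max`, `pct_identity >= identity_min`,
#' `query_coverage_pct >= query_cov_min` and
#' `template_coverage_pct >= template_cov_min`. Rejection reasons are
#' tallied per threshold in the attribute `rejections` (a hit failing
#' several thresholds counts under each).
#'
#' @param hits Tibble of hits (see [read_blast_tab()]): columns `query_id`,
#'   `template_id`, `evalue`, `pct_identity`, `query_coverage_pct`,
#'   `template_coverage_pct`.
#' @param evalue_max,identity_min,query_cov_min,template_cov_min The
#'   thresholds; defaults are the conventional interolog-server settings
#'   (1e-10, 30, 60, 90).
#' @return The surviving hits tibble, with attribute `rejections`.
#' @export
filter_hits <- function(hits, evalue_max = 1e-10, identity_min = 30,
                        query_cov_min = 60, template_cov_min = 90) {
  need <- c("query_id", "template_id", "evalue", "pct_identity",
            "query_coverage_pct", "template_coverage_pct")
  missing_cols <- setdiff(need, names(hits))
  if (length(missing_cols)) {
    abort(sprintf("hits lack column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  fail_e <- !(hits$evalue <= evalue_max)
  fail_i <- !(hits$pct_identity >= identity_min)
  fail_q <- !(hits$query_coverage_pct >= query_cov_min)
  fail_t <- !(hits$template_coverage_pct >= template_cov_min)
  keep <- !(fail_e | fail_i | fail_q | fail_t)
  out <- hits[keep, , drop = FALSE]
  attr(out, "rejections") <- c(evalue = sum(fail_e), identity = sum(fail_i),
                               query_coverage = sum(fail_q),
                               template_coverage = sum(fail_t))
  out
}

canonical_edge <- function(a, b) {
  tibble(template_a = pmin(a, b), template_b = pmax(a, b))
}

#' Predict host-microbe interactions by interolog transfer
#'
#' For every template interaction `(t1, t2)` whose detection method is not
#' excluded, every microbe protein homologous to `t1` combined with every
#' host protein homologous to `t2` (and the symmetric assignment) yields a
#' candidate edge. Hit tables are passed through [filter_hits()] first.
#' Each candidate's joint metrics are worst-of-pair: `joint_evalue` is the
#' larger of the two mapped hit e-values, `joint_identity` the smaller of
#' the two identities; candidates failing `joint_evalue_max` /
#' `joint_identity_min` are dropped. Surviving edges are deduplicated by
#' `(microbe_protein, host_protein)` with supporting template pairs merged
#' (the best joint metrics across supports are kept).
#'
#' @param microbe_hits,host_hits Homology hits of microbe / host query
#'   proteins against template-database proteins.
#' @param template_edges Tibble of template interactions: `template_a`,
#'   `template_b`, `detection_method`.
#' @param exclude_methods Co-complex detection methods to exclude
#'   (case-insensitive substring match on `detection_method`).
#' @param evalue_max,identity_min,query_cov_min,template_cov_min Per-hit
#'   thresholds, passed to [filter_hits()].
#' @param joint_evalue_max,joint_identity_min Joint thresholds applied to
#'   each candidate edge.
#' @return A tibble of class `predicted_ppi`: `microbe_protein`,
#'   `host_protein`, `joint_evalue`, `joint_identity`, `n_templates`,
#'   `templates` (supporting template pairs, `;`-separated).
#' @export
predict_interologs <- function(microbe_hits, host_hits, template_edges,
                               exclude_methods = "tandem affinity purification",
                               evalue_max = 1e-10, identity_min = 30,
                               query_cov_min = 60, template_cov_min = 90,
                               joint_evalue_max = 1e-10,
                               joint_identity_min = 30) {
  stopifnot(all(c("template_a", "template_b") %in% names(template_edges)))
  empty <- tibble(microbe_protein = character(0), host_protein = character(0),
                  joint_evalue = numeric(0), joint_identity = numeric(0),
                  n_templates = integer(0), templates = character(0))
  class(empty) <- c("predicted_ppi", class(empty))
  if (nrow(template_edges) == 0L) {
    warn("empty template interaction set: no predictions")
    return(empty)
  }
  if (!"detection_method" %in% names(template_edges)) {
    template_edges$detection_method <- NA_character_
  }
  excl <- rep(FALSE, nrow(template_edges))
  meth <- tolower(template_edges$detection_method)
  for (m in exclude_methods) {
    excl <- excl | grepl(tolower(m), meth, fixed = TRUE)
  }
  excl[is.na(meth)] <- FALSE
  edges <- template_edges[!excl, , drop = FALSE]
  if (nrow(edges) == 0L) return(empty)

  mh <- filter_hits(microbe_hits, evalue_max, identity_min, query_cov_min,
                    template_cov_min)
  hh <- filter_hits(host_hits, evalue_max, identity_min, query_cov_min,
                    template_cov_min)
  if (nrow(mh) == 0L || nrow(hh) == 0L) return(empty)

  cand <- list()
  # both orientations of each undirected template edge
  dir_edges <- bind_rows(
    tibble(t_microbe = edges$template_a, t_host = edges$template_b,
           pair = paste0(edges$template_a, "--", edges$template_b)),
    tibble(t_microbe = edges$template_b, t_host = edges$template_a,
           pair = paste0(edges$template_a, "--", edges$template_b))) |>
    distinct()
  for (i in seq_len(nrow(dir_edges))) {
    m_sub <- mh[mh$template_id == dir_edges$t_microbe[i], , drop = FALSE]
    h_sub <- hh[hh$template_id == dir_edges$t_host[i], , drop = FALSE]
    if (nrow(m_sub) == 0L || nrow(h_sub) == 0L) next
    grid <- tidyr::expand_grid(mi = seq_len(nrow(m_sub)),
                               hi = seq_len(nrow(h_sub)))
    cand[[length(cand) + 1L]] <- tibble(
      microbe_protein = m_sub$query_id[grid$mi],
      host_protein = h_sub$query_id[grid$hi],
      joint_evalue = pmax(m_sub$evalue[grid$mi], h_sub$evalue[grid$hi]),
      joint_identity = pmin(m_sub$pct_identity[grid$mi],
                            h_sub$pct_identity[grid$hi]),
      template_pair = dir_edges$pair[i])
  }
  if (!length(cand)) return(empty)
  cand <- bind_rows(cand) |>
    filter(.data$joint_evalue <= joint_evalue_max,
           .data$joint_identity >= joint_identity_min)
  if (nrow(cand) == 0L) return(empty)
  out <- cand |>
    group_by(.data$microbe_protein, .data$host_protein) |>
    summarise(joint_evalue = min(.data$joint_evalue),
              joint_identity = max(.data$joint_identity),
              n_templates = dplyr::n_distinct(.data$template_pair),
              templates = paste(sort(unique(.data$template_pair)),
                                collapse = ";"),
              .groups = "drop") |>
    arrange(.data$microbe_protein, .data$host_protein)
  class(out) <- c("predicted_ppi", class(out))
  out
}

#' Summarize a predicted interaction network
#'
#' Counts distinct microbe proteins, host proteins and edges; the
#' immunity-restricted subnetwork (edges whose host protein is in
#' `immunity_genes`); the per-category abundance of annotated host
#' proteins; and the degree of each microbe protein.
#'
#' @param edges A `predicted_ppi` tibble from [predict_interologs()].
#' @param immunity_genes Character vector of immunity-related host protein
#'   ids (optional).
#' @param annotations Optional tibble `host_protein` -> `category`.
#' @return A list with `counts` (one-row tibble), `immunity` (one-row
#'   tibble), `categories` (tibble with counts and percentages over
#'   annotated host proteins) and `degrees` (tibble, microbe-protein
#'   degree list).
#' @export
summarize_network <- function(edges, immunity_genes = character(0),
                              annotations = NULL) {
  counts <- tibble(
    n_microbe_proteins = dplyr::n_distinct(edges$microbe_protein),
    n_host_proteins = dplyr::n_distinct(edges$host_protein),
    n_edges = nrow(edges))
  imm_edges <- edges[edges$host_protein %in% immunity_genes, , drop = FALSE]
  immunity <- tibble(
    n_microbe_proteins = dplyr::n_distinct(imm_edges$microbe_protein),
    n_host_proteins = dplyr::n_distinct(imm_edges$host_protein),
    n_edges = nrow(imm_edges))
  categories <- if (!is.null(annotations)) {
    stopifnot(all(c("host_protein", "category") %in% names(annotations)))
    ann <- distinct(tibble(host_protein = unique(edges$host_protein))) |>
      inner_join(annotations, by = "host_protein")
    if (nrow(ann)) {
      ann |> count(.data$category, name = "n_proteins") |>
        mutate(percent = 100 * .data$n_proteins / sum(.data$n_proteins)) |>
        arrange(desc(.data$n_proteins))
    } else {
      tibble(category = character(0), n_proteins = integer(0),
             percent = numeric(0))
    }
  } else {
    tibble(category = character(0), n_proteins = integer(0),
           percent = numeric(0))
  }
  degrees <- if (nrow(edges)) {
    edges |> count(.data$microbe_protein, name = "degree") |>
      arrange(desc(.data$degree))
  } else {
    tibble(microbe_protein = character(0), degree = integer(0))
  }
  list(counts = counts, immunity = immunity, categories = categories,
       degrees = degrees)
}
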