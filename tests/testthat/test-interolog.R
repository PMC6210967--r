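# Interolog hit filtering, edge prediction against exhaustive cross-join
# enumeration, threshold monotonicity and network summaries.

mk_hits <- function(n, prefix, templates, seed) {
  set.seed(seed)
  tibble::tibble(
    query_id = sprintf("%s%02d", prefix, sample(n, n)),
    template_id = sample(templates, n, replace = TRUE),
    evalue = 10^runif(n, -30, -8),
    pct_identity = runif(n, 25, 80),
    query_coverage_pct = runif(n, 50, 100),
    template_coverage_pct = runif(n, 85, 100))
}

test_that("hit filtering applies all four thresholds with correct comparisons", {
  base <- tibble::tibble(query_id = "q", template_id = "t",
                         evalue = 1e-12, pct_identity = 45,
                         query_coverage_pct = 70, template_coverage_pct = 95)
  expect_identical(nrow(filter_hits(base)), 1L)
  # boundary values survive (>= / <= comparisons)
  edge <- base
  edge$evalue <- 1e-10; edge$pct_identity <- 30
  edge$query_coverage_pct <- 60; edge$template_coverage_pct <- 90
  expect_identical(nrow(filter_hits(edge)), 1L)
  low_id <- base; low_id$pct_identity <- 29.9
  out <- filter_hits(low_id)
  expect_identical(nrow(out), 0L)
  expect_identical(unname(attr(out, "rejections")["identity"]), 1L)

  # 20-hit fixture equals independent application of the four rules
  hits <- mk_hits(20, "q", c("t1", "t2"), seed = 5)
  kept <- filter_hits(hits)
  manual <- hits[hits$evalue <= 1e-10 & hits$pct_identity >= 30 &
                   hits$query_coverage_pct >= 60 &
                   hits$template_coverage_pct >= 90, ]
  expect_equal(tibble::remove_rownames(as.data.frame(kept)),
               tibble::remove_rownames(as.data.frame(manual)),
               ignore_attr = TRUE)
})

good_hit <- function(q, t, ev = 1e-12, id = 50) {
  tibble::tibble(query_id = q, template_id = t, evalue = ev,
                 pct_identity = id, query_coverage_pct = 80,
                 template_coverage_pct = 95)
}

test_that("single template edge transfers exactly one interaction", {
  edges <- tibble::tibble(template_a = "t1", template_b = "t2",
                          detection_method = "yeast two-hybrid")
  ppi <- predict_interologs(good_hit("m1", "t1"), good_hit("h1", "t2"), edges)
  expect_identical(nrow(ppi), 1L)
  expect_identical(ppi$microbe_protein, "m1")
  expect_identical(ppi$host_protein, "h1")

  # the co-complex exclusion removes exactly the excluded-method edges
  tap <- edges
  tap$detection_method <- "Tandem Affinity Purification (TAP)"
  expect_identical(nrow(predict_interologs(good_hit("m1", "t1"),
                                           good_hit("h1", "t2"), tap)), 0L)
  both <- dplyr::bind_rows(edges, tibble::tibble(
    template_a = "t1", template_b = "t2",
    detection_method = "tandem affinity purification"))
  ppi2 <- predict_interologs(good_hit("m1", "t1"), good_hit("h1", "t2"), both)
  expect_identical(nrow(ppi2), 1L)

  expect_warning(predict_interologs(good_hit("m1", "t1"),
                                    good_hit("h1", "t2"),
                                    edges[0, ]), "empty template")
})

test_that("predictions equal brute-force cross-join enumeration on a toy fixture", {
  mhits <- mk_hits(9, "m", c("t1", "t2", "t3"), seed = 11)
  hhits <- mk_hits(12, "h", c("t2", "t3", "t4", "t5"), seed = 12)
  edges <- tibble::tibble(
    template_a = c("t1", "t1", "t2", "t3", "t4"),
    template_b = c("t2", "t4", "t3", "t5", "t5"),
    detection_method = c("two hybrid", "tandem affinity purification",
                         "two hybrid", "coimmunoprecipitation", "two hybrid"))
  got <- predict_interologs(mhits, hhits, edges)

  # oracle: exhaustive enumeration over filtered hits x retained edges,
  # both orientations, then joint-threshold filter and deduplication
  fm <- mhits[mhits$evalue <= 1e-10 & mhits$pct_identity >= 30 &
                mhits$query_coverage_pct >= 60 &
                mhits$template_coverage_pct >= 90, ]
  fh <- hhits[hhits$evalue <= 1e-10 & hhits$pct_identity >= 30 &
                hhits$query_coverage_pct >= 60 &
                hhits$template_coverage_pct >= 90, ]
  keep_e <- !grepl("tandem affinity", edges$detection_method)
  cand <- list()
  for (e in which(keep_e)) {
    for (orient in 1:2) {
      tm <- if (orient == 1) edges$template_a[e] else edges$template_b[e]
      th <- if (orient == 1) edges$template_b[e] else edges$template_a[e]
      for (i in which(fm$template_id == tm)) {
        for (j in which(fh$template_id == th)) {
          je <- max(fm$evalue[i], fh$evalue[j])
          ji <- min(fm$pct_identity[i], fh$pct_identity[j])
          if (je <= 1e-10 && ji >= 30) {
            cand[[length(cand) + 1]] <- c(fm$query_id[i], fh$query_id[j])
          }
        }
      }
    }
  }
  want <- unique(do.call(rbind, cand))
  expect_gt(nrow(want), 0)
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_identical(unname(cbind(got$microbe_protein, got$host_protein)),
                   unname(want))
})

test_that("loosening any single threshold never shrinks the edge set", {
  mhits <- mk_hits(15, "m", c("t1", "t2", "t3"), seed = 21)
  hhits <- mk_hits(15, "h", c("t1", "t2", "t3"), seed = 22)
  edges <- tibble::tibble(template_a = c("t1", "t2"),
                          template_b = c("t2", "t3"),
                          detection_method = "two hybrid")
  base <- predict_interologs(mhits, hhits, edges)
  key <- function(p) paste(p$microbe_protein, p$host_protein)
  looser <- list(
    predict_interologs(mhits, hhits, edges, evalue_max = 1e-5),
    predict_interologs(mhits, hhits, edges, identity_min = 10),
    predict_interologs(mhits, hhits, edges, query_cov_min = 30),
    predict_interologs(mhits, hhits, edges, template_cov_min = 50),
    predict_interologs(mhits, hhits, edges, joint_evalue_max = 1e-5),
    predict_interologs(mhits, hhits, edges, joint_identity_min = 10))
  for (l in looser) expect_true(all(key(base) %in% key(l)))
})

test_that("network summaries count nodes, edges, immunity subnetwork and categories", {
  edges <- tibble::tibble(
    microbe_protein = c("m1", "m1", "m2", "m2", "m3", "m3"),
    host_protein = c("h1", "h2", "h2", "h3", "h4", "h1"),
    joint_evalue = 1e-12, joint_identity = 50, n_templates = 1L,
    templates = "t1--t2")
  ann <- tibble::tibble(host_protein = c("h1", "h2", "h3"),
                        category = c("immune", "immune", "metabolism"))
  s <- summarize_network(edges, immunity_genes = c("h1", "h4"),
                         annotations = ann)
  expect_identical(s$counts$n_microbe_proteins, 3L)
  expect_identical(s$counts$n_host_proteins, 4L)
  expect_identical(s$counts$n_edges, 6L)
  expect_identical(s$immunity$n_edges, 3L)
  expect_identical(s$immunity$n_microbe_proteins, 2L)
  expect_identical(s$immunity$n_host_proteins, 2L)
  expect_equal(sum(s$categories$percent), 100)
  expect_identical(s$degrees$degree[s$degrees$microbe_protein == "m1"], 2L)

  empty <- summarize_network(edges[0, ])
  expect_identical(empty$counts$n_edges, 0L)
  expect_identical(empty$counts$n_microbe_proteins, 0L)
})
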