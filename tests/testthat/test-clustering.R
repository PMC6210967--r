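# Identity computation, the greedy clustering rule (against a naive oracle),
# pan-matrix construction and the core/accessory/unique partition.

test_that("pairwise identity handles the closed-form cases", {
  expect_equal(pairwise_identity("MKVLAHEW", "MKVLAHEW"), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)  # Ala run vs Thr run
  # 100 residues differing at 40 positions, gapless forced alignment
  set.seed(42)
  a <- random_protein(100)
  b <- mutate_protein(a, 40)
  expect_equal(pairwise_identity(a, b), 0.60)
  # symmetry
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # X never counts as identical
  expect_equal(pairwise_identity("XXXX", "XXXX"), 0.0)
})

test_that("greedy clustering degenerate cases", {
  prot <- tibble::tibble(gene_id = sprintf("g%d", 1:4),
                         genome_id = "G1",
                         sequence = rep("MKVLAHEWRRK", 4))
  asn <- greedy_cluster(prot, 0.5)
  expect_length(unique(asn$family_id), 1)

  set.seed(7)
  distinct <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                             genome_id = "G1",
                             sequence = replicate(6, random_protein(60)))
  asn2 <- greedy_cluster(distinct, 0.5)
  expect_length(unique(asn2$family_id), 6)
  expect_error(greedy_cluster(distinct, 1.5), "threshold")
})

test_that("greedy clustering equals the naive quadratic oracle", {
  set.seed(100)
  # 10 base sequences, each with 2 mutated copies: related + unrelated mix
  base <- replicate(10, random_protein(sample(50:90, 1)))
  seqs <- c(base,
            vapply(base, function(s) mutate_protein(s, 5), ""),
            vapply(base, function(s) mutate_protein(s, 15), ""))
  prot <- tibble::tibble(gene_id = sprintf("g%02d", seq_along(seqs)),
                         genome_id = "G1", sequence = unname(seqs))
  oracle <- oracle_greedy(prot, 0.5)
  for (screen in c(0L, 8L)) {
    asn <- greedy_cluster(prot, 0.5, prescreen_kmers = screen)
    got <- asn$family_id[match(oracle$gene_id, asn$gene_id)]
    # identical partitions (family labels may differ)
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(oracle$family,
                                       levels = unique(oracle$family))))
  }
})

test_that("clustering is deterministic and centroids are longest members", {
  set.seed(3)
  base <- random_protein(80)
  prot <- tibble::tibble(
    gene_id = c("b_long", "a_short", "c_mid"),
    genome_id = "G1",
    sequence = c(paste0(base, "AAAA"), substr(base, 1, 70), base))
  a1 <- greedy_cluster(prot, 0.5)
  a2 <- greedy_cluster(prot, 0.5)
  expect_identical(a1, a2)
  expect_true(all(a1$centroid_gene_id == "b_long"))
})

test_that("pan matrix marginals and degenerate shapes are right", {
  asn <- tibble::tibble(gene_id = c("x", "y"), genome_id = c("G1", "G2"),
                        family_id = c("F1", "F1"))
  pan <- build_pan_matrix(asn)
  expect_identical(dim(pan), c(1L, 3L))
  expect_identical(unname(unlist(pan[1, c("G1", "G2")])), c(1L, 1L))

  pan2 <- build_pan_matrix(asn, genomes = c("G1", "G2", "G3"))
  expect_identical(unname(unlist(pan2[1, "G3"])), 0L)
  expect_error(build_pan_matrix(asn, genomes = "G1"), "genome")

  # marginals equal generator truth marginals
  ds <- generate_pangenome(
    pangenome_model(n_genomes = 5, core_families = 10, heaps_kappa = 4,
                    seed = 8),
    evolution_model(seed = 8), sequences = FALSE)
  truth_asn <- dplyr::transmute(ds$genes, gene_id, genome_id, family_id)
  pan3 <- build_pan_matrix(truth_asn)
  m <- as.matrix(pan3[, -1])
  expect_identical(unname(as.integer(colSums(m))),
                   unname(as.integer(table(ds$genes$genome_id)[colnames(m)])))
  expect_identical(unname(as.integer(rowSums(m))),
                   unname(as.integer(table(ds$genes$family_id)[pan3$family_id])))
})

test_that("partition splits families into core, accessory, unique", {
  ones <- random_pan_matrix(5, 4, p = 1)
  ones[, -1] <- 1L
  expect_true(all(partition_pan(ones)$class == "core"))

  ident <- random_pan_matrix(4, 4, p = 0)
  ident[, -1] <- diag(4)
  expect_true(all(partition_pan(ident)$class == "unique"))

  set.seed(5)
  pan <- random_pan_matrix(50, 6)
  part <- partition_pan(pan)
  expect_setequal(part$family_id, pan$family_id)
  occ <- rowSums(as.matrix(pan[, -1]) > 0)
  expect_identical(part$class[match(pan$family_id, part$family_id)],
                   unname(ifelse(occ == 6, "core",
                                 ifelse(occ == 1, "unique", "accessory"))))
})

test_that("clustering at 0.50 recovers true families when classes are separable", {
  # within-family protein identity >= 70%, between-family ~ random (<= 30%)
  ds <- generate_pangenome(
    pangenome_model(n_genomes = 6, core_families = 25,
                    openness_mode = "closed", pool_size = 40,
                    pool_presence = 0.5,
                    family_length_codons = list(mean = 80, min = 40),
                    seed = 17),
    evolution_model(omega_target = 0.2, ks_target = 0.3, seed = 17))
  prot <- dplyr::transmute(ds$genes, gene_id, genome_id, sequence = protein)
  asn <- greedy_cluster(prot, 0.5)
  joined <- dplyr::inner_join(asn, ds$genes[, c("gene_id", "family_id")],
                              by = "gene_id", suffix = c("", "_true"))
  tab <- dplyr::count(joined, family_id, family_id_true)
  expect_identical(nrow(tab), length(unique(tab$family_id)))
  expect_identical(nrow(tab), length(unique(tab$family_id_true)))
})
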