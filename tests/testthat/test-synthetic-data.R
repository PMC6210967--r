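# The generator's contracts: sequence invariants, truth-table closure,
# determinism, and recoverability of its planted structure.

small_open <- function(seed = 5, ...) {
  generate_pangenome(
    pangenome_model(n_genomes = 6, core_families = 12, heaps_kappa = 6,
                    heaps_gamma = 0.3,
                    family_length_codons = list(mean = 40, min = 20),
                    seed = seed),
    evolution_model(omega_target = 0.2, ks_target = 0.4, seed = seed), ...)
}

test_that("every CDS is a translatable sense-codon sequence and proteins match", {
  ds <- small_open()
  expect_true(all(nchar(ds$genes$cds) %% 3 == 0))
  expect_true(all(substr(ds$genes$cds, 1, 3) %in% oracle_sense_codons()))
  # no internal stops, and protein == standard-code translation, every record
  expect_identical(unname(translate_cds(ds$genes$cds)), ds$genes$protein)
  expect_false(any(grepl("\\*", ds$genes$protein)))
})

test_that("truth table closure: every gene appears exactly once, families consistent", {
  ds <- small_open()
  expect_false(anyDuplicated(ds$genes$gene_id) > 0)
  expect_setequal(unique(ds$genes$family_id), ds$families$family_id)
  # gene ids encode genome and family
  parsed <- strsplit(ds$genes$gene_id, "|", fixed = TRUE)
  expect_identical(vapply(parsed, `[`, "", 1), ds$genes$genome_id)
  expect_identical(vapply(parsed, `[`, "", 2), ds$genes$family_id)
  # core families are present in every genome
  core <- ds$families$family_id[ds$families$class == "core"]
  n_gen <- length(unique(ds$genes$genome_id))
  counts <- table(ds$genes$family_id[ds$genes$family_id %in% core])
  expect_true(all(counts == n_gen))
})

test_that("identical model and seed give identical output; seeds differ otherwise", {
  a <- small_open(seed = 9)
  b <- small_open(seed = 9)
  expect_identical(a$genes, b$genes)
  expect_identical(a$families, b$families)
  c <- small_open(seed = 10)
  expect_false(identical(a$genes$cds, c$genes$cds))
})

test_that("omega 0 forbids nonsynonymous change: one protein per family", {
  ds <- generate_pangenome(
    pangenome_model(n_genomes = 5, core_families = 8, heaps_kappa = 3,
                    family_length_codons = list(mean = 40, min = 20),
                    seed = 2),
    evolution_model(omega_target = 0, ks_target = 0.6, seed = 2))
  per_fam <- tapply(ds$genes$protein, ds$genes$family_id,
                    function(x) length(unique(x)))
  expect_true(all(per_fam == 1))
})

test_that("degenerate closed pool (all core) gives identical family content", {
  ds <- generate_pangenome(
    pangenome_model(n_genomes = 5, core_families = 10,
                    openness_mode = "closed", pool_size = 10, seed = 3),
    evolution_model(seed = 3), sequences = FALSE)
  content <- tapply(ds$genes$family_id, ds$genes$genome_id,
                    function(x) paste(sort(x), collapse = ","))
  expect_length(unique(content), 1)
})

test_that("open-mode distinct-family growth follows the requested Heaps exponent", {
  ds <- generate_pangenome(
    pangenome_model(n_genomes = 60, core_families = 100, heaps_kappa = 120,
                    heaps_gamma = 0.3, seed = 11),
    evolution_model(seed = 11), sequences = FALSE)
  # cumulative distinct families in the fixed generation order G001..G060
  genomes <- sprintf("G%03d", 1:60)
  seen <- character(0)
  pan <- numeric(60)
  for (i in seq_along(genomes)) {
    seen <- union(seen, ds$genes$family_id[ds$genes$genome_id == genomes[i]])
    pan[i] <- length(seen)
  }
  # generation-order growth exponent; the core offset biases it slightly
  # above heaps_gamma at small n (the rarefied-curve fit is checked elsewhere)
  slope <- unname(coef(lm(log(pan) ~ log(seq_len(60))))[2])
  expect_gt(slope, 0.25)
  expect_lt(slope, 0.45)
})

test_that("unreachable divergence targets fail loudly, naming the constraint", {
  expect_error(evolution_model(ks_target = 5), "saturation")
  expect_error(pangenome_model(n_genomes = 1), "n_genomes")
  expect_error(pangenome_model(heaps_gamma = 1.2), "heaps_gamma")
  expect_error(pangenome_model(openness_mode = "closed", core_families = 50,
                               pool_size = 10), "pool_size")
})

test_that("feature table plants the requested Spearman structure", {
  planted <- tibble::tibble(feature = c("mono", "strong", "none"),
                            rho = c(1, 0.8, 0))
  ft <- generate_feature_table(56, planted, seed = 4)
  r1 <- spearman(ft$genome_size_bp, ft$mono)
  expect_equal(r1$rho, 1)
  r2 <- spearman(ft$genome_size_bp, ft$strong)
  expect_gt(r2$rho, 0.7)
  expect_lt(r2$rho, 0.9)
  # negative targets flip the direction
  ftn <- generate_feature_table(
    40, tibble::tibble(feature = "anti", rho = 0.8, direction = "negative"),
    seed = 5)
  expect_lt(spearman(ftn$genome_size_bp, ftn$anti)$rho, -0.6)
})

test_that("null features give uniform Spearman p-values over replicate seeds", {
  ps <- vapply(1:500, function(s) {
    ft <- generate_feature_table(
      56, tibble::tibble(feature = "none", rho = 0), seed = s)
    spearman(ft$genome_size_bp, ft$none)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("written datasets round-trip through standard formats", {
  ds <- small_open(seed = 13)
  dir <- withr::local_tempdir()
  man <- write_pangenome(ds, dir)
  expect_true(all(file.exists(man$protein), file.exists(man$cds)))
  g1 <- man$genome_id[1]
  prot <- read_fasta_tbl(man$protein[1], genome_id = g1)
  back <- ds$genes[ds$genes$genome_id == g1, ]
  expect_setequal(prot$gene_id, back$gene_id)
  expect_identical(prot$sequence[match(back$gene_id, prot$gene_id)],
                   back$protein)
  truth <- read_tsv_table(file.path(dir, "truth_families.tsv"))
  expect_identical(nrow(truth), nrow(ds$families))
})
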