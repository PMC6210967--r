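# Nei-Gojobori machinery: site counts, pathway-averaged differences (against
# recursive enumeration), the pairwise estimator and the family aggregate.

test_that("site counts match the genetic code for canonical codons", {
  sc <- ng_site_counts(c("TTT", "ATG"))
  expect_equal(sc$s, c(1 / 3, 0))
  expect_equal(sc$n, c(8 / 3, 3))
  # s + n = 3 for every sense codon
  all61 <- ng_site_counts(oracle_sense_codons())
  expect_equal(all61$s + all61$n, rep(3, 61))
  expect_error(ng_site_counts("TAA"), "stop")
  expect_error(ng_site_counts("NNT"), "sense")
})

test_that("difference counts average mutational pathways correctly", {
  expect_equal(ng_differences("TTT", "TTC")[, c("s_d", "n_d")],
               tibble::tibble(s_d = 1, n_d = 0))
  # TTT -> GTA: via GTT (nonsyn, syn) and via TTA (nonsyn, nonsyn)
  expect_equal(ng_differences("TTT", "GTA")[, c("s_d", "n_d")],
               tibble::tibble(s_d = 0.5, n_d = 1.5))
  expect_equal(unlist(ng_differences("AAA", "AAA")[, c("s_d", "n_d")],
                      use.names = FALSE), c(0, 0))
  # s_d + n_d equals the Hamming distance (spot check, random pairs)
  set.seed(14)
  sense <- oracle_sense_codons()
  for (i in 1:50) {
    ab <- sample(sense, 2)
    d <- ng_differences(ab[1], ab[2])
    hamming <- sum(strsplit(ab[1], "")[[1]] != strsplit(ab[2], "")[[1]])
    expect_equal(d$s_d + d$n_d, hamming)
  }
})

test_that("pairwise Ka/Ks matches the enumeration oracle and is symmetric", {
  set.seed(15)
  for (i in 1:20) {
    a <- random_cds(30)
    b <- random_cds(30)
    got <- ng_kaks(a, b)
    want <- oracle_ng_kaks(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
    expect_equal(got$s_d, want$s_d, tolerance = 1e-12)
    expect_equal(got$n_d, want$n_d, tolerance = 1e-12)
    expect_equal(got$S + got$N, 3 * got$n_codons)
    rev <- ng_kaks(b, a)
    expect_equal(as.data.frame(got), as.data.frame(rev))
  }
})

test_that("identical, saturated and gap-containing pairs are flagged correctly", {
  same <- ng_kaks("ATGAAACCC", "ATGAAACCC")
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_identical(same$flag, "undefined_omega")
  expect_true(is.na(same$omega))

  # all-synonymous Leu wobble: p_s = 1.5 >= 3/4 saturates the correction
  sat <- ng_kaks(strrep("TTA", 20), strrep("TTG", 20))
  expect_identical(sat$flag, "saturated")

  gap <- ng_kaks("ATG---AAA", "ATGCCCAAA")
  expect_equal(gap$n_codons, 2L)
})

test_that("codon alignment passes equal-length families through and gaps insertions", {
  fam <- tibble::tibble(gene_id = c("a", "b"),
                        cds = c("ATGAAACCCGGG", "ATGAAACCTGGG"))
  aln <- codon_align(fam)
  expect_identical(aln$aligned_cds, fam$cds)

  # one sequence with a two-codon insertion: exactly two gapped columns
  ins <- tibble::tibble(
    gene_id = c("a", "b"),
    cds = c("ATGAAAGATCTGATTGAAGAACGTCTG", "ATGAAAGATCTGAAACTGATTGAAGAACGTCTG"))
  aln2 <- codon_align(ins)
  expect_identical(unique(nchar(aln2$aligned_cds)), max(nchar(ins$cds)))
  gaps <- vapply(aln2$aligned_cds, function(s) {
    sum(substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3)) == "---")
  }, numeric(1))
  expect_equal(sum(gaps), 2)

  # internal stops are dropped with a message
  expect_message(
    codon_align(tibble::tibble(gene_id = c("ok", "bad"),
                               cds = c("ATGAAACCC", "ATGTAACCC"))),
    "internal stop")
})

test_that("family omega aggregates valid pairs and counts exclusions", {
  fam <- tibble::tibble(
    gene_id = c("a", "b"),
    aligned_cds = c("ATGAAACCCGGGTTTGCAGAA", "ATGAAGCCCGGGTTCGCAGAA"))
  agg <- family_omega(fam)
  pair <- ng_kaks(fam$aligned_cds[1], fam$aligned_cds[2])
  expect_equal(agg$Ka, pair$Ka)
  expect_equal(agg$Ks, pair$Ks)
  expect_equal(agg$n_pairs, 1L)

  # family with saturated members: excluded pairs counted, not dropped
  tri <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    aligned_cds = c(paste0("ATGAAACCC", strrep("TTA", 15)),
                    paste0("ATGAAGCCC", strrep("TTA", 15)),
                    paste0("ATGAAACCC", strrep("TTG", 15))))
  agg3 <- family_omega(tri)
  expect_equal(agg3$n_pairs, 3L)
  expect_equal(agg3$n_excluded, 2L)
  expect_identical(agg3$flag, "ok")

  allbad <- tibble::tibble(gene_id = c("a", "b"),
                           aligned_cds = c(strrep("TTA", 10), strrep("TTG", 10)))
  expect_identical(family_omega(allbad)$flag, "no_valid_pair")
})

test_that("omega estimates recover the generator's target on a small run", {
  set.seed(44)
  om <- vapply(1:40, function(i) {
    p <- simulate_cds_pair(200, omega_target = 0.2, ks_target = 0.5)
    ng_kaks(p$cds[1], p$cds[2])$omega
  }, numeric(1))
  expect_gt(mean(om), 0.13)
  expect_lt(mean(om), 0.27)
})
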