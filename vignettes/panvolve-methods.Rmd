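---
title: "Models and methods behind panvolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panvolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panvolve` analyzes collections of bacterial genomes — the motivating case
is a genus of probiotic, gut-adapted bacteria sampled as a few dozen
assemblies — through five connected questions: how gene content is
structured (families; core/accessory/unique), whether the pan-genome is
open, how strong and of what kind the selection on the core is, which
per-genome features co-vary with genome size, and which host proteins the
core proteome may interact with. This vignette records the models, the
defaults and why they are set as they are, and the design decisions taken
where the methodology is genuinely underdetermined.

## Gene families by greedy centroid clustering

Orthologous families are built with the single-pass greedy rule used by
USEARCH-style tools: proteins are sorted by decreasing length (ties broken
lexicographically by gene id, making the procedure fully deterministic)
and each sequence joins the first existing centroid whose identity to it
reaches the threshold, otherwise it founds a new family. Because insertion
order is length-descending, the centroid is always the longest member of
its family.

Two details are fixed here because the clustering literature leaves them
tool-specific, and results are only reproducible bit-for-bit once they are
pinned down:

* **Identity definition.** Global Needleman–Wunsch/Gotoh alignment with
  BLOSUM62, gap open 10, gap extension 0.5; identity = identical aligned
  residue pairs / alignment columns *excluding terminal-gap columns*. `X`
  never counts as a match.
* **Word prescreen.** Before aligning a query against a centroid, the two
  sorted 4-mer sets are intersected; centroids sharing fewer than
  `prescreen_kmers` (default 8) 4-mers are skipped. At the default 50%
  threshold this is conservative in practice — two proteins at ≥ 50%
  identity over ≥ 50 residues essentially always share dozens of 4-mers,
  while unrelated pairs share none or a handful — and it reduces the
  alignment workload by roughly an order of magnitude. Setting
  `prescreen_kmers = 0` disables the screen and gives the literal
  quadratic rule; the test suite checks the two modes agree with a naive
  reference implementation.

The default threshold of 0.50 is the conventional within-genus ortholog
cut-off. No re-clustering, centroid updating, paralog splitting or synteny
is attempted: one pass, one partition.

## Rarefaction and the openness call

For each of (by default) 30 random genome orderings, `pan(n)` counts
families seen in the first `n` genomes and `core(n)` the families present
in all of them. Medians across iterations (not means) feed the fits, to
damp permutation outliers; both are reported.

Fitted forms: Heaps' law `pan(n) = κ·n^γ` by least squares in log-log
space, and `core(n) = c + a·exp(−n/τ)` by nonlinear least squares (several
τ starting values are tried; with noiseless curves `nls` needs a
`scaleOffset` to accept a perfect fit).

**Verdict rule.** Calling openness from the cumulative fit alone is
unreliable: a finite gene pool sampled with fixed probabilities produces a
saturating pan curve whose log-log slope is small but significantly
positive (γ̂ ≈ 0.04 with a confidence interval excluding zero on our
closed-mode synthetic data), so "γ > 0 with CI excluding 0" would call
nearly everything open. The package therefore uses the standard new-gene
criterion: fit the per-step new-family counts `new(n) = pan(n) − pan(n−1)`
to `κ'·n^(−α)` and call the pan-genome **open** iff the 95% upper
confidence bound of α̂ is below 1 — exactly the condition under which the
Heaps series diverges. γ̂ and its interval are still estimated and
reported from the cumulative fit, where they are informative about the
growth rate (on synthetic data with a planted exponent of 0.3 the
cumulative fit recovers ≈ 0.33–0.35; the small upward bias comes from the
constant core offset at small `n`). Degenerate inputs are well-defined:
constant pan curves give γ̂ = 0, α̂ = ∞ and verdict closed.

At 20 genomes the α interval is typically too wide to exclude 1; around 60
genomes the call is stable across seeds in both directions. This is a
property of the statistics, not a defect: openness genuinely cannot be
asserted from a handful of genomes.

## Codon-usage relative entropy

For a gene set, observed sense-codon frequencies `p` are compared with an
expected distribution `q` by `D_KL(p‖q) = Σ p·log2(p/q)` (bits; log base
is a scale choice only — the downstream Welch test is invariant to it).
Stop codons are never counted; codons containing ambiguous bases are
skipped.

The construction of `q` is the one genuinely open modeling choice, so two
explicit nulls are provided:

* `positional_nucleotide` (default): `q(xyz) ∝ f1(x)·f2(y)·f3(z)` from the
  position-specific nucleotide frequencies of the same gene set,
  renormalized over the 61 sense codons. This is the "no codon-level
  structure beyond composition" null and needs no external input.
* `uniform_synonymous`: each amino acid's observed frequency split equally
  among its synonymous codons — the "no codon preference" null.

Per genome, `genome_relative_entropy()` computes the DKL of a designated
subset (the core genes) and of the whole chromosome (all genes), each
against its own expected model, and `compare_core_vs_chromosome()` applies
Welch's unequal-variance t-test (Welch–Satterthwaite df, two-sided and
one-sided p for core > chromosome; the zero-variance-equal-means corner
returns t = 0, p = 1).

One statistical caveat is documented rather than hidden: the core genes
are a subset of the chromosome of the *same* genome, so the two per-genome
DKL series are positively coupled and the two-sample test is conservative
under the null. The test suite verifies type-I control (the rejection rate
under a generator null does not exceed the nominal level); exact
nominality would require disjoint gene sets and would no longer be the
comparison practitioners run.

## Nei–Gojobori Ka/Ks

Per sense codon, each of the 9 single-nucleotide changes is classified
against the standard code; the synonymous site count `s` is the sum of
per-position synonymous fractions, and mutations to stop codons count as
nonsynonymous — this keeps `s + n = 3` exactly, which the tests assert for
all 61 codons. Between two codons, synonymous/nonsynonymous step counts
are averaged over all minimal mutational pathways, excluding pathways
through stop codons; when every pathway is blocked, the stop-inclusive set
is used and the pair flagged. The full 61 × 61 table is precomputed once
per session and checked in the tests against an independent recursive
enumeration.

For an aligned pair (gap-containing codon columns excluded), `p_s = s_d/S`
and `p_n = n_d/N` are Jukes–Cantor corrected,
`d = −(3/4)·ln(1 − (4/3)p)`; ω = Ka/Ks. Records are flagged rather than
coerced: `undefined_omega` when Ks = 0 (never reported as 0 or ∞),
`saturated` when a proportion reaches the 3/4 ceiling. Family-level ω
averages pairwise Ka and Ks over defined, unsaturated pairs and reports
the exclusion count.

Codon alignments come from protein alignments back-translated to codons.
Families whose proteins share one length are aligned positionally; MAFFT
handles length-variable families. Columns with a gap in any sequence are
excluded from counting globally.

The estimator's calibration is validated by simulation: at a true ω of
0.2 and pairwise Ks ≈ 0.5 over 300 codons, the mean of 200 ω̂ values lands
within ±0.05 of the target and every estimate stays below 1; at ω = 1 the
mean lands in [0.9, 1.1]. The slight downward bias at ω = 1 (~5%) comes
from stop-codon rejection suppressing a small fraction of nonsynonymous
events, which the NG counting does not model.

## Comparative statistics

Spearman's ρ is the Pearson correlation of average ranks. The p-value
scheme is split by sample size — exact full-enumeration permutation below
n = 10, t-approximation with n − 2 df from n = 10 — because the
t-approximation is poor exactly where enumeration is cheap. Constant
inputs yield an explicit `constant_input` flag, not a silent NA.
Correlations with genome size exclude the `R`, `S` and `MC` COG bins by
convention (poorly characterized or ambiguous function); multi-class genes
are counted once under `MC`. Kruskal–Wallis delegates to
`stats::kruskal.test` (tie-corrected H, χ² p on k − 1 df), with the
all-identical corner defined as H = 0, p = 1. The peptide scan is a plain
sliding window reporting exact hits and ≤ `max_mismatch` variants
separately, with mismatch positions and residues.

## Interolog transfer

A template interaction (t1, t2) transfers to every (microbe, host) protein
pair mapping to (t1, t2) or (t2, t1) through homology hits that pass all
four per-hit thresholds (e-value ≤ 1e−10, identity ≥ 30, query coverage ≥
60, template coverage ≥ 90 — the conventional server settings). Because
the original server's joint-score formula is not public, the joint metrics
are defined as **worst-of-pair**: joint e-value = max of the two hit
e-values, joint identity = min of the two identities — the conservative
choice, and one that changes edge counts, hence stated prominently. Edges
are undirected, deduplicated by protein pair with supporting templates
merged, and co-complex detection methods (tandem affinity purification by
default) are excluded by case-insensitive substring match. The tests
verify exhaustive-enumeration equivalence and that loosening any single
threshold never shrinks the edge set.

## The synthetic-data generator

The generator exists so every stage can be checked against planted truth;
its defaults are one fixed set of study conditions, not tuning knobs.

* **Structure.** Open mode: genome *i* (in a fixed generation order)
  introduces `Poisson(κ·i^(γ−1))` new accessory families; previously seen
  accessory families recur with probability `m/i` (m = genomes carrying
  the family so far). The recurrence rule is what makes genomes
  exchangeable — without it all accessory families are unique to their
  introducing genome and rarefaction under random orderings is linear, so
  no Heaps exponent could be recovered. Closed mode: a finite pool, core
  families everywhere, each non-core pool family present per genome with a
  fixed probability (default 0.5, which saturates the pan curve within
  ~20 genomes).
* **Sequences.** Family ancestors are sampled codon-wise (amino acids
  uniform; each amino acid's preferred codon up-weighted by
  `exp(bias)`, with class-specific bias for core vs non-core). Each
  genome's copy evolves by per-codon uniform single-nucleotide proposals
  at rate `3d` per codon (branch length d = Ks/2), accepting synonymous
  proposals always, nonsynonymous with probability ω, and rejecting stop
  codons. Under this process the NG assumptions hold by construction
  (uniform substitution, no transition bias), which is what makes ω̂
  recovery a meaningful calibration check rather than a tautology — the
  estimator is counting-based, the generator event-based.
* **Genome-level bias variation.** An optional synonymous
  codon-preference sweep re-draws a fraction of each gene copy's codons
  within their synonymous family at a genome-specific bias intensity
  (`genome_bias_sd` around the class value). It models strain-to-strain
  variation in translational selection, changes no protein, and gives
  per-genome entropy values genuine genome-level variance — without it,
  all between-genome variation in DKL is gene-pool sampling noise shared
  across genomes, and no genome-level test can be calibrated.
* **Feature tables.** Planted genome-size correlations use a Gaussian
  copula: a latent normal with Pearson correlation `2·sin(πρ/6)` to the
  genome-size latent yields the requested Spearman ρ; targets of ±1
  degenerate to pure monotone transforms (ρ exactly ±1) and 0 to an
  independent column (verified to give uniform p-values over 500 seeds).

What the generator does **not** emulate: real gene length and amino-acid
composition distributions, paralogy, horizontal transfer of sequence
blocks, genomic-island/IS/prophage *sequences* (mobilome quantities enter
only as feature-table counts), transition/transversion bias, and
among-site rate variation. Passing tests on this generator therefore
demonstrate correctness of the implemented statistics under their own
assumptions, not robustness to every property of real genome data.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make the statistics
informative while keeping a full run comfortable on one core: openness
recovery at 60 genomes × 10 seeds (structure only), family recovery at 20
genomes × 400 core families (~9,000 proteins clustered), ω calibration at
2 × 200 pairs × 300 codons, the entropy contrast at 56 genomes, and the
entropy null calibration at 500 replicate seeds of a 6-genome
configuration. Seeds are fixed everywhere; `generate_pangenome()` is
byte-deterministic given model and seed, and the pipeline derives
per-stage seeds from one global seed by fixed offsets so stages can be
rerun in isolation.

Tie-breaks and degenerate inputs are defined, not accidental: clustering
ties break lexicographically; empty genomes yield all-zero pan-matrix
columns; constant pan curves classify closed without error; Welch on two
zero-variance equal groups returns p = 1; ω on identical sequences is
undefined, not zero.

## Known limitations

* Greedy single-pass clustering depends on the length ordering; it is the
  faithful rendering of the referenced tool family, not a globally optimal
  partition.
* The openness call needs tens of genomes for power, and the α criterion
  assumes the new-gene counts follow a single power law over the observed
  range.
* NG Ka/Ks is a counting method: no transition/transversion weighting, no
  codon-frequency weighting, no ML (GY94-style) model, and saturation is
  flagged rather than modeled.
* The entropy comparison is conservative by construction (core ⊂
  chromosome); it controls, but does not exactly attain, its nominal
  level under the null.
* Interolog predictions inherit every bias of the template set and the
  worst-of-pair joint score; counts are not comparable across different
  template databases.
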