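#include <Rcpp.h>
using namespace Rcpp;

// Per-codon substitution sampler for the synthetic-sequence generator.
// Each codon receives Poisson(3*d) uniform single-nucleotide proposals;
// proposals creating stop codons are rejected, synonymous proposals are
// accepted with probability 1, nonsynonymous with probability omega.
// `neigh` maps (sense codon, proposal 0..8) to the 0-based index of the
// resulting sense codon, or -1 when the result is a stop; `syn` flags
// synonymous proposals. Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
IntegerVector cpp_evolve_codons(IntegerVector codons, double d, double omega,
                                IntegerMatrix neigh, IntegerMatrix syn) {
  int L = codons.size();
  IntegerVector out(L);
  for (int i = 0; i < L; ++i) {
    int cur = codons[i];
    int np = (int)R::rpois(3.0 * d);
    for (int k = 0; k < np; ++k) {
      int prop = (int)(unif_rand() * 9.0);
      if (prop > 8) prop = 8;
      int tgt = neigh(cur, prop);
      if (tgt < 0) continue;  // stop codon: rejected
      if (syn(cur, prop) == 1) {
        cur = tgt;
      } else if (unif_rand() < omega) {
        cur = tgt;
      }
    }
    out[i] = cur;
  }
  return out;
}
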