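#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) protein alignment with affine gaps and a
// substitution matrix, plus the greedy centroid clustering loop. The identity
// convention is fixed package-wide: identical aligned residue pairs divided by
// alignment columns excluding terminal-gap columns; 'X' never counts as a match.

namespace {

struct SubMat {
  double score[128][128];
  SubMat(const NumericMatrix& m, const std::vector<std::string>& alpha) {
    for (int i = 0; i < 128; ++i)
      for (int j = 0; j < 128; ++j) score[i][j] = -4.0;
    int n = alpha.size();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        score[(int)alpha[i][0]][(int)alpha[j][0]] = m(i, j);
  }
};

struct AlnStats {
  int matches;
  int columns_internal;  // alignment columns excluding terminal-gap columns
  double score;
};

// Gotoh global alignment with traceback; gap_open is the cost of the first
// gap position (opening), gap_ext of each further position.
AlnStats align_pair(const std::string& a, const std::string& b,
                    const SubMat& sm, double gap_open, double gap_ext) {
  const int la = a.size(), lb = b.size();
  const double NEG = -1e30;
  // DP matrices: M (match/mismatch), X (gap in b, consume a), Y (gap in a).
  // Workspace buffers are reused across calls (single-threaded R session);
  // they are resized, then fully (re)initialized below.
  static std::vector<double> M, X, Y;
  static std::vector<uint8_t> tbM, tbX, tbY;
  const size_t need = (size_t)(la + 1) * (lb + 1);
  M.assign(need, NEG); X.assign(need, NEG); Y.assign(need, NEG);
  tbM.assign(need, 0); tbX.assign(need, 0); tbY.assign(need, 0);
  auto idx = [lb](int i, int j) { return i * (lb + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[idx(i, 0)] = -gap_open - gap_ext * (i - 1);
    tbX[idx(i, 0)] = 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[idx(0, j)] = -gap_open - gap_ext * (j - 1);
    tbY[idx(0, j)] = 2;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int ij = idx(i, j), di = idx(i - 1, j), dj = idx(i, j - 1),
                dd = idx(i - 1, j - 1);
      double s = sm.score[(int)a[i - 1]][(int)b[j - 1]];
      // M
      double m0 = M[dd], m1 = X[dd], m2 = Y[dd];
      if (m0 >= m1 && m0 >= m2) { M[ij] = m0 + s; tbM[ij] = 0; }
      else if (m1 >= m2)        { M[ij] = m1 + s; tbM[ij] = 1; }
      else                      { M[ij] = m2 + s; tbM[ij] = 2; }
      // X: gap in b (move in a)
      double xo = M[di] - gap_open, xe = X[di] - gap_ext, xy = Y[di] - gap_open;
      if (xo >= xe && xo >= xy) { X[ij] = xo; tbX[ij] = 0; }
      else if (xe >= xy)        { X[ij] = xe; tbX[ij] = 1; }
      else                      { X[ij] = xy; tbX[ij] = 2; }
      // Y: gap in a (move in b)
      double yo = M[dj] - gap_open, yx = X[dj] - gap_open, ye = Y[dj] - gap_ext;
      if (yo >= yx && yo >= ye) { Y[ij] = yo; tbY[ij] = 0; }
      else if (yx >= ye)        { Y[ij] = yx; tbY[ij] = 1; }
      else                      { Y[ij] = ye; tbY[ij] = 2; }
    }
  }
  // traceback from best end state
  int state;
  const int end = idx(la, lb);
  double best = M[end]; state = 0;
  if (X[end] > best) { best = X[end]; state = 1; }
  if (Y[end] > best) { best = Y[end]; state = 2; }

  // reconstruct column types: 0 = aligned pair, 1 = gap in b, 2 = gap in a
  std::vector<uint8_t> cols;
  std::vector<char> ca, cb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      uint8_t prev = tbM[idx(i, j)];
      cols.push_back(0); ca.push_back(a[i - 1]); cb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      uint8_t prev = tbX[idx(i, j)];
      cols.push_back(1); ca.push_back(a[i]); cb.push_back(0);
      --i; state = prev;
    } else {
      uint8_t prev = tbY[idx(i, j)];
      cols.push_back(2); ca.push_back(0); cb.push_back(b[j]);
      --j; state = prev;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(cols.begin(), cols.end());
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());

  // terminal gap runs: leading/trailing columns that are gaps (in either seq)
  int lead = 0, trail = 0, n = cols.size();
  while (lead < n && cols[lead] != 0) ++lead;
  while (trail < n - lead && cols[n - 1 - trail] != 0) ++trail;

  AlnStats st;
  st.score = best;
  st.columns_internal = n - lead - trail;
  st.matches = 0;
  for (int k = lead; k < n - trail; ++k) {
    if (cols[k] == 0 && ca[k] == cb[k] && ca[k] != 'X') ++st.matches;
  }
  return st;
}

std::vector<uint32_t> kmer_set(const std::string& s, int k) {
  std::vector<uint32_t> out;
  if ((int)s.size() < k) return out;
  for (size_t i = 0; i + k <= s.size(); ++i) {
    uint32_t h = 0;
    for (int j = 0; j < k; ++j) h = h * 27u + (uint32_t)(s[i + j] - 'A');
    out.push_back(h);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

int shared_count(const std::vector<uint32_t>& x, const std::vector<uint32_t>& y) {
  int c = 0;
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (y[j] < x[i]) ++j;
    else { ++c; ++i; ++j; }
  }
  return c;
}

}  // namespace

// [[Rcpp::export]]
List cpp_align_identity(std::string a, std::string b, NumericMatrix submat,
                        CharacterVector alphabet, double gap_open,
                        double gap_ext) {
  std::vector<std::string> alpha = as<std::vector<std::string>>(alphabet);
  SubMat sm(submat, alpha);
  AlnStats st = align_pair(a, b, sm, gap_open, gap_ext);
  double id = st.columns_internal > 0
                  ? (double)st.matches / (double)st.columns_internal
                  : 0.0;
  return List::create(_["identity"] = id, _["matches"] = st.matches,
                      _["columns"] = st.columns_internal,
                      _["score"] = st.score);
}

// Greedy centroid clustering: sequences must already be in processing order
// (length-descending, ties lexicographic by id). Each sequence joins the
// first centroid (in founding order) with identity >= threshold, else founds
// a new family. prescreen_kmers > 0 skips centroids sharing fewer than that
// many 4-mers with the query (0 disables the screen).
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 NumericMatrix submat, CharacterVector alphabet,
                                 double gap_open, double gap_ext,
                                 int prescreen_kmers) {
  std::vector<std::string> alpha = as<std::vector<std::string>>(alphabet);
  SubMat sm(submat, alpha);
  const int n = seqs.size();
  std::vector<std::string> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);

  std::vector<int> centroid_idx;                 // founding order
  std::vector<std::vector<uint32_t>> centroid_kmers;
  IntegerVector assign(n);

  for (int i = 0; i < n; ++i) {
    std::vector<uint32_t> qk;
    if (prescreen_kmers > 0) qk = kmer_set(sv[i], 4);
    int hit = -1;
    for (size_t c = 0; c < centroid_idx.size(); ++c) {
      if (prescreen_kmers > 0 &&
          shared_count(qk, centroid_kmers[c]) < prescreen_kmers)
        continue;
      AlnStats st = align_pair(sv[i], sv[centroid_idx[c]], sm, gap_open, gap_ext);
      double id = st.columns_internal > 0
                      ? (double)st.matches / (double)st.columns_internal
                      : 0.0;
      if (id >= threshold) { hit = (int)c; break; }
    }
    if (hit < 0) {
      centroid_idx.push_back(i);
      if (prescreen_kmers > 0) centroid_kmers.push_back(kmer_set(sv[i], 4));
      else centroid_kmers.push_back(std::vector<uint32_t>());
      hit = (int)centroid_idx.size() - 1;
    }
    assign[i] = hit + 1;  // 1-based family index in founding order
    if ((i & 127) == 0) Rcpp::checkUserInterrupt();
  }
  return assign;
}
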