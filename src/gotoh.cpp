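#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// position-score matrix S (n x m): S(i,j) is the score of pairing position
// i of A with position j of B. A gap of length L costs open + L * extend.
// Ties are broken deterministically: diagonal (match layer), then up (gap
// in B, consuming A), then left (gap in A, consuming B); the traceback
// recomputes each cell's argmax with the same preference order, so forward
// and backward passes agree exactly. The same kernel serves
// residue-residue and profile-profile alignment; the caller builds S.
//
// Returns list(score, path): path is a k x 2 integer matrix of 1-based
// indices into A and B, 0 marking a gap.

static inline int argmax3(double m, double u, double l) {
  // preference on ties: M (0) > U (1) > L (2)
  if (m >= u && m >= l) return 0;
  if (u >= l) return 1;
  return 2;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend,
                 bool free_ends = false) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), U(n + 1, m + 1), L(n + 1, m + 1);
  M(0, 0) = 0.0; U(0, 0) = NEG; L(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    U(i, 0) = free_ends ? 0.0 : -gap_open - gap_extend * i;
    L(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    U(0, j) = NEG;
    L(0, j) = free_ends ? 0.0 : -gap_open - gap_extend * j;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dm = M(i - 1, j - 1), du = U(i - 1, j - 1),
             dl = L(i - 1, j - 1);
      M(i, j) = std::max(dm, std::max(du, dl)) + S(i - 1, j - 1);
      double uo = M(i - 1, j) - gap_open - gap_extend;
      double ue = U(i - 1, j) - gap_extend;
      double ul = L(i - 1, j) - gap_open - gap_extend;
      U(i, j) = std::max(uo, std::max(ue, ul));
      double lo = M(i, j - 1) - gap_open - gap_extend;
      double le = L(i, j - 1) - gap_extend;
      double lu = U(i, j - 1) - gap_open - gap_extend;
      L(i, j) = std::max(lo, std::max(le, lu));
    }
  }
  int ei = n, ej = m;
  int layer = argmax3(M(n, m), U(n, m), L(n, m));
  double score = (layer == 0) ? M(n, m) : (layer == 1 ? U(n, m) : L(n, m));
  if (free_ends) {
    // trailing gaps are free: end at the best cell on the last row/column
    for (int jj = 0; jj <= m; ++jj) {
      int lay = argmax3(M(n, jj), U(n, jj), L(n, jj));
      double v = (lay == 0) ? M(n, jj) : (lay == 1 ? U(n, jj) : L(n, jj));
      if (v > score) { score = v; ei = n; ej = jj; layer = lay; }
    }
    for (int ii = 0; ii <= n; ++ii) {
      int lay = argmax3(M(ii, m), U(ii, m), L(ii, m));
      double v = (lay == 0) ? M(ii, m) : (lay == 1 ? U(ii, m) : L(ii, m));
      if (v > score) { score = v; ei = ii; ej = m; layer = lay; }
    }
  }
  std::vector<int> ai, bi;
  // free trailing region first (emitted, but cost-free)
  for (int jj = m; jj > ej; --jj) { ai.push_back(0); bi.push_back(jj); }
  for (int ii = n; ii > ei; --ii) { ai.push_back(ii); bi.push_back(0); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (i == 0) {            // only horizontal moves remain
      ai.push_back(0); bi.push_back(j); --j; continue;
    }
    if (j == 0) {            // only vertical moves remain
      ai.push_back(i); bi.push_back(0); --i; continue;
    }
    if (layer == 0) {
      ai.push_back(i); bi.push_back(j);
      layer = argmax3(M(i - 1, j - 1), U(i - 1, j - 1), L(i - 1, j - 1));
      --i; --j;
    } else if (layer == 1) {
      ai.push_back(i); bi.push_back(0);
      layer = argmax3(M(i - 1, j) - gap_open - gap_extend,
                      U(i - 1, j) - gap_extend,
                      L(i - 1, j) - gap_open - gap_extend);
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      layer = argmax3(M(i, j - 1) - gap_open - gap_extend,
                      U(i, j - 1) - gap_open - gap_extend,
                      L(i, j - 1) - gap_extend);
      // note: preference among the three source layers is M > U > L
      --j;
    }
  }
  const int k = (int)ai.size();
  IntegerMatrix path(k, 2);
  for (int t = 0; t < k; ++t) {
    path(t, 0) = ai[k - 1 - t];
    path(t, 1) = bi[k - 1 - t];
  }
  return List::create(_["score"] = score, _["path"] = path);
}
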