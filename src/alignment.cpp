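#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gotoh global alignment with affine gaps over a precomputed position-score
// matrix, so one kernel serves both residue-residue and profile-profile
// alignment. A gap of length k costs gap_open + (k-1)*gap_extend.
// Returns the optimal score and aligned index paths (0 = gap).
// [[Rcpp::export]]
List nw_affine_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: state at the predecessor cell (0 = M, 1 = X, 2 = Y)
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1), tY((n + 1) * W, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_extend;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double best = M[d];
      signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + S(i - 1, j - 1);
      tM[c] = arg;
      // X: a[i] against a gap in b; switching from a gap in a re-opens
      best = M[u] + gap_open; arg = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; arg = 1; }
      if (Y[u] + gap_open   > best) { best = Y[u] + gap_open;   arg = 2; }
      X[c] = best;
      tX[c] = arg;
      best = M[l] + gap_open; arg = 0;
      if (X[l] + gap_open   > best) { best = X[l] + gap_open;   arg = 1; }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; arg = 2; }
      Y[c] = best;
      tY[c] = arg;
    }
  }
  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }
  std::vector<int> ai, bi;
  ai.reserve(n + m);
  bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0)      { ai.push_back(i); bi.push_back(j); state = tM[c]; --i; --j; }
    else if (state == 1) { ai.push_back(i); bi.push_back(0); state = tX[c]; --i; }
    else                 { ai.push_back(0); bi.push_back(j); state = tY[c]; --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}

namespace {
// last: 0 = substitution / start, 1 = inside gap run in b, 2 = gap run in a
double bf_rec(const NumericMatrix& S, int i, int j, int last, double acc,
              double go, double ge) {
  const int n = S.nrow(), m = S.ncol();
  if (i == n && j == m) return acc;
  double best = -1e30, v;
  if (i < n && j < m) {
    v = bf_rec(S, i + 1, j + 1, 0, acc + S(i, j), go, ge);
    if (v > best) best = v;
  }
  if (i < n) {
    v = bf_rec(S, i + 1, j, 1, acc + (last == 1 ? ge : go), go, ge);
    if (v > best) best = v;
  }
  if (j < m) {
    v = bf_rec(S, i, j + 1, 2, acc + (last == 2 ? ge : go), go, ge);
    if (v > best) best = v;
  }
  return best;
}
} // namespace

// Exhaustive maximum over every global alignment (all monotone edit paths,
// carrying the gap-run state for affine costs). Exponential in sequence
// length: an independent oracle for short sequences, not a user-facing path.
// [[Rcpp::export]]
double bf_align_score_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  return bf_rec(S, 0, 0, 0, 0.0, gap_open, gap_extend);
}
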