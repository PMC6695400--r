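#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed pair-score matrix
// S (n x m): S(i-1, j-1) is the score for aligning position i of A with
// position j of B. A gap of length L costs gap_open + gap_extend * (L - 1).
// Works for sequence-sequence (substitution lookups) and profile-sequence
// (expected profile scores) alignment alike.
// Returns the optimal score plus 1-based aligned index vectors (0 = gap).
// [[Rcpp::export(name = ".gotoh_cpp")]]
List gotoh_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: A-position aligned to gap (vertical); Y: B-position aligned to gap.
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);
  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + gap_extend * (i - 1));
    tX(i, 0) = 1;  // came from X
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = -(gap_open + gap_extend * (j - 1));
    tY(0, j) = 2;  // came from Y
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double best = M(i - 1, j - 1);
      int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = best + S(i - 1, j - 1);
      tM(i, j) = arg;
      // X (consume A_i against a gap)
      best = M(i - 1, j) - gap_open;
      arg = 0;
      if (X(i - 1, j) - gap_extend > best) {
        best = X(i - 1, j) - gap_extend;
        arg = 1;
      }
      if (Y(i - 1, j) - gap_open > best) {
        best = Y(i - 1, j) - gap_open;
        arg = 2;
      }
      X(i, j) = best;
      tX(i, j) = arg;
      // Y (consume B_j against a gap)
      best = M(i, j - 1) - gap_open;
      arg = 0;
      if (X(i, j - 1) - gap_open > best) {
        best = X(i, j - 1) - gap_open;
        arg = 1;
      }
      if (Y(i, j - 1) - gap_extend > best) {
        best = Y(i, j - 1) - gap_extend;
        arg = 2;
      }
      Y(i, j) = best;
      tY(i, j) = arg;
    }
  }
  double score = M(n, m);
  int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      ai.push_back(i);
      bi.push_back(j);
      --i;
      --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      ai.push_back(i);
      bi.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tY(i, j);
      ai.push_back(0);
      bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}
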