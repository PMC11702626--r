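#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap global alignment (Needleman-Wunsch / Gotoh, three-state DP).
//
// a, b: 1-based integer codes into `sub`; code 0 marks a residue absent from
// the matrix and is scored at the matrix minimum (mismatch floor).
// A gap of length k costs gap_open for its first column plus
// gap_extend * (k - 1) for the remainder; switching gap rows opens anew.
// Tie-breaks are pinned so alignments are bit-reproducible: at equal score
// the match state (diagonal) is preferred over a gap in the target row (up),
// which is preferred over a gap in the source row (left) -- both when
// choosing the final state and when choosing each predecessor.
//
// Returns ops (1 = diagonal, 2 = up, 3 = left, in alignment order) + score.
// [[Rcpp::export]]
List gotoh_align_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;

  double sub_min = R_PosInf;
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < sub.ncol(); ++j)
      if (sub(i, j) < sub_min) sub_min = sub(i, j);

  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  std::vector<signed char> bM(sz, -1), bX(sz, -1), bY(sz, -1);
  const int W = m + 1;
#define AT(i, j) ((size_t)(i) * W + (j))

  M[AT(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[AT(i, 0)] = gap_open + (i - 1) * gap_extend;
    bX[AT(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[AT(0, j)] = gap_open + (j - 1) * gap_extend;
    bY[AT(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1];
      const double s = (ai > 0 && bj > 0) ? sub(ai - 1, bj - 1) : sub_min;

      double best = M[AT(i - 1, j - 1)];
      signed char bs = 0;
      if (X[AT(i - 1, j - 1)] > best) { best = X[AT(i - 1, j - 1)]; bs = 1; }
      if (Y[AT(i - 1, j - 1)] > best) { best = Y[AT(i - 1, j - 1)]; bs = 2; }
      M[AT(i, j)] = best + s;
      bM[AT(i, j)] = bs;

      best = M[AT(i - 1, j)] + gap_open; bs = 0;
      if (X[AT(i - 1, j)] + gap_extend > best) { best = X[AT(i - 1, j)] + gap_extend; bs = 1; }
      if (Y[AT(i - 1, j)] + gap_open > best) { best = Y[AT(i - 1, j)] + gap_open; bs = 2; }
      X[AT(i, j)] = best;
      bX[AT(i, j)] = bs;

      best = M[AT(i, j - 1)] + gap_open; bs = 0;
      if (X[AT(i, j - 1)] + gap_open > best) { best = X[AT(i, j - 1)] + gap_open; bs = 1; }
      if (Y[AT(i, j - 1)] + gap_extend > best) { best = Y[AT(i, j - 1)] + gap_extend; bs = 2; }
      Y[AT(i, j)] = best;
      bY[AT(i, j)] = bs;
    }
  }

  int st = 0;
  double score = M[AT(n, m)];
  if (X[AT(n, m)] > score) { score = X[AT(n, m)]; st = 1; }
  if (Y[AT(n, m)] > score) { score = Y[AT(n, m)]; st = 2; }

  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      ops.push_back(1);
      st = bM[AT(i, j)];
      --i; --j;
    } else if (st == 1) {
      ops.push_back(2);
      st = bX[AT(i, j)];
      --i;
    } else {
      ops.push_back(3);
      st = bY[AT(i, j)];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
#undef AT
  return List::create(_["ops"] = wrap(ops), _["score"] = score);
}
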