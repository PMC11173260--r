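#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment of two alignment profiles.
//
// profA, profB: 21 x width matrices of per-column character frequencies
// (rows 0..19 = canonical residues in alphabetical order, row 20 = gap).
// sub: 20 x 20 substitution matrix in the same residue order.
// Column-vs-column score is the expected substitution score over residue
// pairs; gap characters inside a profile contribute nothing.
// gapOpen/gapExt are positive penalties. Ties in the traceback prefer
// diagonal, then a gap in B, then a gap in A, which makes the merge
// deterministic.
//
// Returns an integer vector of moves from the start of the alignment:
// 1 = column from both profiles, 2 = column from A only (gap in B),
// 3 = column from B only (gap in A).
// [[Rcpp::export(name = ".profileAlignCpp")]]
IntegerVector profileAlignCpp(NumericMatrix profA, NumericMatrix profB,
                              NumericMatrix sub, double gapOpen,
                              double gapExt) {
  const int n = profA.ncol(), m = profB.ncol();
  const double NEG = -1e100;

  // precompute column-vs-column expected substitution scores
  NumericMatrix s(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double v = 0.0;
      for (int a = 0; a < 20; ++a) {
        double fa = profA(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < 20; ++b) {
          double fb = profB(b, j);
          if (fb != 0.0) v += fa * fb * sub(a, b);
        }
      }
      s(i, j) = v;
    }
  }

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in B (consumes A)
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in A (consumes B)
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -gapOpen - gapExt * (i - 1);
  for (int j = 1; j <= m; ++j) Y[idx(0, j)] = -gapOpen - gapExt * (j - 1);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M[idx(i - 1, j - 1)],
                    std::max(X[idx(i - 1, j - 1)], Y[idx(i - 1, j - 1)]));
      M[idx(i, j)] = diag + s(i - 1, j - 1);
      // no direct gap-to-gap transitions: a gap run in one profile must be
      // closed by an aligned column before one opens in the other, which
      // rules out staggered gap pairs standing in for a single mismatch
      X[idx(i, j)] = std::max(M[idx(i - 1, j)] - gapOpen,
                              X[idx(i - 1, j)] - gapExt);
      Y[idx(i, j)] = std::max(M[idx(i, j - 1)] - gapOpen,
                              Y[idx(i, j - 1)] - gapExt);
    }
  }

  // traceback, preferring M > X > Y at equal scores
  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  int state;  // 0 = M, 1 = X, 2 = Y
  {
    double best = M[idx(n, m)];
    state = 0;
    if (X[idx(n, m)] > best) { best = X[idx(n, m)]; state = 1; }
    if (Y[idx(n, m)] > best) { best = Y[idx(n, m)]; state = 2; }
  }
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      moves.push_back(1);
      double prev = M[idx(i, j)] - s(i - 1, j - 1);
      --i; --j;
      if (std::abs(M[idx(i, j)] - prev) < 1e-9) state = 0;
      else if (std::abs(X[idx(i, j)] - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1 || (state == 0 && j == 0)) {
      moves.push_back(2);
      double cur = X[idx(i, j)];
      --i;
      if (i > 0 && std::abs(X[idx(i, j)] - gapExt - cur) < 1e-9) state = 1;
      else state = 0;
    } else {
      moves.push_back(3);
      double cur = Y[idx(i, j)];
      --j;
      if (j > 0 && std::abs(Y[idx(i, j)] - gapExt - cur) < 1e-9) state = 2;
      else state = 0;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
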