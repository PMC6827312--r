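#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Needleman-Wunsch,
// Gotoh three-state). Profiles are 20 x L residue-frequency matrices
// (gaps contribute zero mass). Column-pair score is the expected
// substitution score f1' S f2. Returns the traceback as a vector of moves
// from the start of the alignment: 1 = column of profile A only,
// 2 = column of profile B only, 3 = aligned column pair.
// [[Rcpp::export]]
IntegerVector profile_align_path(NumericMatrix f1, NumericMatrix f2,
                                 NumericMatrix sub, double gap_open,
                                 double gap_ext) {
  const int L1 = f1.ncol(), L2 = f2.ncol(), A = sub.nrow();
  const double NEG = -1e30;
  // column-pair scores s(i,j) = f1(.,i)' S f2(.,j)
  NumericMatrix g1(A, L1);
  for (int i = 0; i < L1; ++i)
    for (int b = 0; b < A; ++b) {
      double acc = 0.0;
      for (int a = 0; a < A; ++a) acc += f1(a, i) * sub(a, b);
      g1(b, i) = acc;
    }
  NumericMatrix s(L1, L2);
  for (int i = 0; i < L1; ++i)
    for (int j = 0; j < L2; ++j) {
      double acc = 0.0;
      for (int b = 0; b < A; ++b) acc += g1(b, i) * f2(b, j);
      s(i, j) = acc;
    }
  const int R = L1 + 1, C = L2 + 1;
  std::vector<double> M(R * C, NEG), X(R * C, NEG), Y(R * C, NEG);
  // predecessor state of each cell, per state: 0 = M, 1 = X, 2 = Y
  std::vector<signed char> pM(R * C, -1), pX(R * C, -1), pY(R * C, -1);
  auto at = [C](int i, int j) { return i * C + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= L1; ++i) {
    X[at(i, 0)] = -gap_open - gap_ext * i;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= L2; ++j) {
    Y[at(0, j)] = -gap_open - gap_ext * j;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= L1; ++i)
    for (int j = 1; j <= L2; ++j) {
      const int d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1),
                c = at(i, j);
      // M from best of diagonal predecessors
      double best = M[d]; signed char pb = 0;
      if (X[d] > best) { best = X[d]; pb = 1; }
      if (Y[d] > best) { best = Y[d]; pb = 2; }
      M[c] = best + s(i - 1, j - 1);
      pM[c] = pb;
      // X: gap in profile B (consume A column)
      double xo = std::max(M[u], Y[u]) - gap_open - gap_ext;
      double xe = X[u] - gap_ext;
      if (xe >= xo) { X[c] = xe; pX[c] = 1; }
      else { X[c] = xo; pX[c] = (M[u] >= Y[u]) ? 0 : 2; }
      // Y: gap in profile A (consume B column)
      double yo = std::max(M[l], X[l]) - gap_open - gap_ext;
      double ye = Y[l] - gap_ext;
      if (ye >= yo) { Y[c] = ye; pY[c] = 2; }
      else { Y[c] = yo; pY[c] = (M[l] >= X[l]) ? 0 : 1; }
    }
  // traceback from the best end state
  std::vector<int> rev;
  int i = L1, j = L2;
  int state = 0;
  {
    const int c = at(i, j);
    double best = M[c];
    if (X[c] > best) { best = X[c]; state = 1; }
    if (Y[c] > best) { state = 2; }
  }
  while (i > 0 || j > 0) {
    const int c = at(i, j);
    if (state == 0) {
      rev.push_back(3);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      rev.push_back(1);
      state = pX[c]; --i;
    } else {
      rev.push_back(2);
      state = pY[c]; --j;
    }
  }
  IntegerVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size() - 1 - k];
  return path;
}
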