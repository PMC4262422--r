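#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh three-state DP).
// Profiles are column frequency matrices (alphabet x columns); the last
// alphabet row is the gap character, which scores 0 against everything
// (the substitution matrix passed in has zero gap row/column).
// Returns the score and the merged column path: 1 = columns from both,
// 2 = column from A only (gap in B), 3 = column from B only.
//
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix pa, NumericMatrix pb, NumericMatrix sub,
                       double gapOpen, double gapExt) {
  const int K = pa.nrow();
  const int la = pa.ncol(), lb = pb.ncol();
  if (pb.nrow() != K || sub.nrow() != K || sub.ncol() != K)
    stop("alphabet dimensions disagree");
  const double NEG = -1e18;
  // expected substitution score between column i of A and column j of B
  std::vector<double> sc((size_t) la * lb);
  for (int i = 0; i < la; i++)
    for (int j = 0; j < lb; j++) {
      double s = 0.0;
      for (int a = 0; a < K; a++) {
        double fa = pa(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < K; b++) {
          double fb = pb(b, j);
          if (fb != 0.0) s += fa * fb * sub(a, b);
        }
      }
      sc[(size_t) i * lb + j] = s;
    }
  std::vector<double> M((size_t)(la + 1) * (lb + 1), NEG);
  std::vector<double> X(M), Y(M);  // X: gap in B (consume A), Y: gap in A
  std::vector<signed char> tbM(M.size(), 0), tbX(M.size(), 0), tbY(M.size(), 0);
  auto at = [&](int i, int j) -> size_t { return (size_t) i * (lb + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= la; i++) {
    X[at(i, 0)] = -gapOpen - (i - 1) * gapExt;
    tbX[at(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= lb; j++) {
    Y[at(0, j)] = -gapOpen - (j - 1) * gapExt;
    tbY[at(0, j)] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= la; i++) {
    for (int j = 1; j <= lb; j++) {
      double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)], dy = Y[at(i - 1, j - 1)];
      double best = dm; signed char t = 1;
      if (dx > best) { best = dx; t = 2; }
      if (dy > best) { best = dy; t = 3; }
      M[at(i, j)] = best + sc[(size_t)(i - 1) * lb + (j - 1)];
      tbM[at(i, j)] = t;
      double xo = M[at(i - 1, j)] - gapOpen, xe = X[at(i - 1, j)] - gapExt;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 1; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 2; }
      double yo = M[at(i, j - 1)] - gapOpen, ye = Y[at(i, j - 1)] - gapExt;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
    }
  }
  int i = la, j = lb;
  double sm = M[at(i, j)], sx = X[at(i, j)], sy = Y[at(i, j)];
  double score = sm; int state = 0;
  if (sx > score) { score = sx; state = 1; }
  if (sy > score) { score = sy; state = 2; }
  std::vector<int> path;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char t = tbM[at(i, j)];
      path.push_back(1); i--; j--;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {
      signed char t = tbX[at(i, j)];
      path.push_back(2); i--;
      state = (t == 1) ? 0 : 1;
    } else {
      signed char t = tbY[at(i, j)];
      path.push_back(3); j--;
      state = (t == 1) ? 0 : 2;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score, _["path"] = wrap(path));
}
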