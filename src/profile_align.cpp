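#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment (Gotoh, affine gaps) over a
// precomputed column-score matrix C (rows = profile A columns, cols =
// profile B columns).  A gap of length k costs go + k*ge, matching the
// pairwise-alignment convention used elsewhere in the package.
// Returns the move path (0 = both, 1 = A column vs gap, 2 = gap vs B
// column) with the alignment score as an attribute.
// [[Rcpp::export]]
IntegerVector profile_align_path(NumericMatrix C, double go, double ge) {
  const int n = C.nrow(), m = C.ncol();
  const double NEG = -1e18;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which state preceded (0=M,1=X,2=Y)
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) { X(i, 0) = -go - i * ge; tX(i, 0) = 1; }
  X(1, 0) = -go - ge; tX(1, 0) = 0;
  for (int j = 1; j <= m; ++j) { Y(0, j) = -go - j * ge; tY(0, j) = 2; }
  Y(0, 1) = -go - ge; tY(0, 1) = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume one column of each
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      int t = 0; double best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      M(i, j) = best + C(i - 1, j - 1); tM(i, j) = t;
      // X: A column against gap
      a = M(i - 1, j) - go - ge; b = X(i - 1, j) - ge; c = Y(i - 1, j) - go - ge;
      t = 0; best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      X(i, j) = best; tX(i, j) = t;
      // Y: gap against B column
      a = M(i, j - 1) - go - ge; b = X(i, j - 1) - go - ge; c = Y(i, j - 1) - ge;
      t = 0; best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      Y(i, j) = best; tY(i, j) = t;
    }
  }
  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  std::vector<int> rev;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(0); state = tM(i, j); --i; --j;
    } else if (state == 1) {
      rev.push_back(1); state = tX(i, j); --i;
    } else {
      rev.push_back(2); state = tY(i, j); --j;
    }
  }
  IntegerVector path(rev.rbegin(), rev.rend());
  path.attr("score") = best;
  return path;
}
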