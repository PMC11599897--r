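#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping between two value sequences with squared-difference
// local cost and symmetric steps (diagonal, horizontal, vertical, all unit
// weight). Returns the non-normalized path cost plus, for each index of x,
// the mean matched index of y (and vice versa), from which warped timings
// are derived in R.
// [[Rcpp::export]]
List dtw_core(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty sequence");
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 diag, 1 up (i-1), 2 left (j-1)
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = x[i] - y[j];
      c *= c;
      if (i == 0 && j == 0) { D(i, j) = c; from(i, j) = -1; continue; }
      double best = R_PosInf; int arg = -1;
      if (i > 0 && j > 0 && D(i - 1, j - 1) < best) { best = D(i - 1, j - 1); arg = 0; }
      if (i > 0 && D(i - 1, j) < best) { best = D(i - 1, j); arg = 1; }
      if (j > 0 && D(i, j - 1) < best) { best = D(i, j - 1); arg = 2; }
      D(i, j) = best + c;
      from(i, j) = arg;
    }
  }
  // backtrack, accumulating matched index sums
  NumericVector xsum(n), xcnt(n), ysum(m), ycnt(m);
  int i = n - 1, j = m - 1;
  while (true) {
    xsum[i] += j; xcnt[i] += 1;
    ysum[j] += i; ycnt[j] += 1;
    int f = from(i, j);
    if (f < 0) break;
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
  }
  NumericVector xmap(n), ymap(m);
  for (int k = 0; k < n; ++k) xmap[k] = xsum[k] / xcnt[k];
  for (int k = 0; k < m; ++k) ymap[k] = ysum[k] / ycnt[k];
  return List::create(_["cost"] = D(n - 1, m - 1),
                      _["xmap"] = xmap, _["ymap"] = ymap);
}
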