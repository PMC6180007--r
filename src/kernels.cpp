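#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Product over coordinates of cos(a * (x_i - y_i)) for all row pairs of X
// and Y.  Uses cos(a(x-y)) = cos(ax)cos(ay) + sin(ax)sin(ay) so the
// transcendentals are evaluated once per matrix entry instead of once per
// output-cell coordinate; the accumulation is then pure multiply-add over
// contiguous columns.
// [[Rcpp::export]]
arma::mat cosprod_cross(const arma::mat& X, const arma::mat& Y, double a) {
  const uword n = X.n_rows, k = Y.n_rows, m = X.n_cols;
  if (Y.n_cols != m) Rcpp::stop("dimension mismatch in cosprod_cross");
  mat CX = trans(cos(a * X)), SX = trans(sin(a * X));   // m x n
  mat CY = trans(cos(a * Y)), SY = trans(sin(a * Y));   // m x k
  mat P(n, k);
  for (uword j = 0; j < k; ++j) {
    const double* cy = CY.colptr(j);
    const double* sy = SY.colptr(j);
    for (uword i = 0; i < n; ++i) {
      const double* cx = CX.colptr(i);
      const double* sx = SX.colptr(i);
      // four independent accumulators keep the multiply pipeline full
      double p0 = 1.0, p1 = 1.0, p2 = 1.0, p3 = 1.0;
      uword t = 0;
      for (; t + 4 <= m; t += 4) {
        p0 *= cx[t] * cy[t] + sx[t] * sy[t];
        p1 *= cx[t + 1] * cy[t + 1] + sx[t + 1] * sy[t + 1];
        p2 *= cx[t + 2] * cy[t + 2] + sx[t + 2] * sy[t + 2];
        p3 *= cx[t + 3] * cy[t + 3] + sx[t + 3] * sy[t + 3];
      }
      for (; t < m; ++t)
        p0 *= cx[t] * cy[t] + sx[t] * sy[t];
      P(i, j) = (p0 * p1) * (p2 * p3);
    }
  }
  return P;
}
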