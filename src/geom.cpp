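#include "peds.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_dist_segments(NumericMatrix pts, NumericMatrix segs) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = walls_dist(pts(i, 0), pts(i, 1), segs);
  return out;
}

// even-odd rule with an on-boundary tolerance (boundary counts as inside)
// [[Rcpp::export]]
LogicalVector cpp_in_polygon(NumericMatrix pts, NumericMatrix poly, double tol) {
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = point_in_poly(pts(i, 0), pts(i, 1), poly, tol);
  return out;
}

// [[Rcpp::export]]
double cpp_polygon_area(NumericMatrix poly) {
  int m = poly.nrow();
  double a = 0.0;
  for (int j = 0, k = m - 1; j < m; k = j++)
    a += poly(k, 0) * poly(j, 1) - poly(j, 0) * poly(k, 1);
  return std::fabs(a) / 2.0;
}
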