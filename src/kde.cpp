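#include <Rcpp.h>
using namespace Rcpp;

// Accumulate quartic (biweight) kernel density from weighted sample points
// onto a north-up square-cell grid.
//
// Each sample point j carries weight w[j] (the arc length of road it
// represents, metres). The density at a cell centre is
//   sum_j w[j] * K(d_j / h),  K(u) = (3 / pi) * (1 - u^2)^2 / h^2  for u < 1
// so that the kernel integrates to 1 over the plane and the grid total
// (density * cell area) approximates total line length.
//
// [[Rcpp::export]]
NumericMatrix kde_accumulate(NumericVector px, NumericVector py,
                             NumericVector w, double h,
                             int nrow, int ncol,
                             double x0, double y0, double cell) {
  NumericMatrix out(nrow, ncol);
  const double h2 = h * h;
  const double norm = 3.0 / (M_PI * h2);
  const int n = px.size();
  for (int j = 0; j < n; ++j) {
    const double x = px[j], y = py[j], wj = w[j];
    // candidate cell index window (1-based maths, clamped)
    int c_lo = (int)std::ceil((x - h - x0) / cell + 0.5);
    int c_hi = (int)std::floor((x + h - x0) / cell + 0.5);
    int r_lo = (int)std::ceil((y0 - (y + h)) / cell + 0.5);
    int r_hi = (int)std::floor((y0 - (y - h)) / cell + 0.5);
    if (c_lo < 1) c_lo = 1;
    if (c_hi > ncol) c_hi = ncol;
    if (r_lo < 1) r_lo = 1;
    if (r_hi > nrow) r_hi = nrow;
    for (int r = r_lo; r <= r_hi; ++r) {
      const double yc = y0 - (r - 0.5) * cell;
      const double dy2 = (yc - y) * (yc - y);
      if (dy2 >= h2) continue;
      for (int c = c_lo; c <= c_hi; ++c) {
        const double xc = x0 + (c - 0.5) * cell;
        const double d2 = (xc - x) * (xc - x) + dy2;
        if (d2 < h2) {
          const double t = 1.0 - d2 / h2;
          out(r - 1, c - 1) += wj * norm * t * t;
        }
      }
    }
  }
  return out;
}
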