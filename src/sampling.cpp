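#include <Rcpp.h>
using namespace Rcpp;

// Bilinear interpolation of img at 0-based pixel-centered coordinates
// (x, y); x indexes columns, y rows.  Out-of-bounds samples return fill.
// [[Rcpp::export(name = ".bilinear_sample_cpp")]]
NumericVector bilinear_sample_cpp(const NumericMatrix& img,
                                  const NumericVector& x,
                                  const NumericVector& y,
                                  double fill) {
  const int M = img.nrow(), W = img.ncol();
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double* p = img.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    double xs = x[k], ys = y[k];
    if (!(xs >= 0.0 && xs <= W - 1.0 && ys >= 0.0 && ys <= M - 1.0)) {
      out[k] = fill;
      continue;
    }
    int x0 = (int)xs, y0 = (int)ys;
    if (x0 > W - 2) x0 = W - 2;
    if (y0 > M - 2) y0 = M - 2;
    if (x0 < 0) x0 = 0;          // degenerate single-column/row images
    if (y0 < 0) y0 = 0;
    double fx = xs - x0, fy = ys - y0;
    const double* c0 = p + (R_xlen_t)x0 * M + y0;
    double v00 = c0[0];
    double v10 = (M > 1) ? c0[1] : v00;
    double v01 = (W > 1) ? c0[M] : v00;
    double v11 = (W > 1) ? ((M > 1) ? c0[M + 1] : c0[M]) : v10;
    out[k] = (1.0 - fx) * ((1.0 - fy) * v00 + fy * v10) +
             fx * ((1.0 - fy) * v01 + fy * v11);
  }
  return out;
}
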