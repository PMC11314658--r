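#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad (second-order-section) IIR filter, direct form II transposed.
// sos: k x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.
// zi:  k x 2 matrix of initial conditions per section (may be all zero).
// Returns the filtered signal; final states are written back into zi_out.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(const NumericMatrix& sos, const NumericVector& x,
                          NumericMatrix zi) {
  const int k = sos.nrow();
  const int n = x.size();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  if (zi.nrow() != k || zi.ncol() != 2) stop("zi must be k x 2");
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi + z2 - a1 * yi;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
    zi(s, 0) = z1;
    zi(s, 1) = z2;
  }
  return y;
}
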