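#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Mixture-of-kernels von Mises KDE evaluated at theta:
//   mean_i exp(kappa * (cos(theta_j - x_i) - 1)) / (2 * pi * I0e(kappa))
// i0e is the exponentially scaled Bessel I0(kappa), computed in R so the
// e^kappa factors cancel and large concentrations stay finite.
// cos(t - x) is expanded through precomputed sin/cos of the data points so
// the inner loop is a single exp per kernel.
// [[Rcpp::export]]
NumericVector vm_kde_eval_cpp(NumericVector theta, NumericVector data,
                              double kappa, double i0e) {
  const int m = theta.size(), n = data.size();
  NumericVector out(m);
  std::vector<double> cx(n), sx(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = std::cos(data[i]);
    sx[i] = std::sin(data[i]);
  }
  const double norm = 2.0 * M_PI * i0e * static_cast<double>(n);
  for (int j = 0; j < m; ++j) {
    const double ct = std::cos(theta[j]), st = std::sin(theta[j]);
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += std::exp(kappa * (ct * cx[i] + st * sx[i] - 1.0));
    out[j] = s / norm;
  }
  return out;
}
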