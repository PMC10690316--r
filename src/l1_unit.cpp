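#include <Rcpp.h>
using namespace Rcpp;

// Inner PMD step: w = S(a, delta) / ||S(a, delta)||_2 with the smallest
// delta >= 0 (bisection) such that ||w||_1 <= c. Hot loop of the sparse
// CCA alternations, hence in C++.

// [[Rcpp::export(name = ".l1_unit_vector")]]
NumericVector l1_unit_vector(const NumericVector& a, double c, double tol) {
  const int p = a.size();
  double amax = 0.0, ss = 0.0, s1 = 0.0;
  for (int j = 0; j < p; ++j) {
    const double aj = std::fabs(a[j]);
    if (aj > amax) amax = aj;
    ss += a[j] * a[j];
  }
  if (amax == 0.0) stop("input vector is identically zero");
  NumericVector w(p);
  const double l2 = std::sqrt(ss);
  for (int j = 0; j < p; ++j) { w[j] = a[j] / l2; s1 += std::fabs(w[j]); }
  if (s1 <= c + 1e-12) return w;

  double lo = 0.0, hi = amax;
  while (hi - lo > tol) {
    const double mid = 0.5 * (lo + hi);
    double n1 = 0.0, n2 = 0.0;
    for (int j = 0; j < p; ++j) {
      const double sj = std::fabs(a[j]) - mid;
      if (sj > 0.0) { n1 += sj; n2 += sj * sj; }
    }
    if (n1 > c * std::sqrt(n2)) lo = mid; else hi = mid;
  }
  double n2 = 0.0;
  for (int j = 0; j < p; ++j) {
    const double sj = std::fabs(a[j]) - hi;
    w[j] = (sj > 0.0) ? ((a[j] > 0.0) ? sj : -sj) : 0.0;
    n2 += w[j] * w[j];
  }
  const double nrm = std::sqrt(n2);
  for (int j = 0; j < p; ++j) w[j] /= nrm;
  return w;
}
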