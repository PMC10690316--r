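#include <Rcpp.h>
using namespace Rcpp;

// Weighted elastic-net coordinate descent over a decreasing lambda path.
//
// Minimizes, for each lambda,
//   (1 / (2 * nscale)) * sum_i w_i (y_i - x_i' beta)^2
//     + lambda * sum_j pf_j (alpha |beta_j| + 0.5 (1 - alpha) beta_j^2)
// with warm starts along the path and active-set cycling. nscale is passed
// by the caller (the number of original samples) so that augmented rows
// encoding a quadratic agreement penalty do not change the loss scale.
//
// No intercept: callers either center y (gaussian) or supply an explicit
// unpenalized intercept column (binomial IRLS).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_enet_path")]]
NumericMatrix cd_enet_path(const NumericMatrix& X, const NumericVector& y,
                           const NumericVector& w, const NumericVector& lambda,
                           double alpha, const NumericVector& penalty_factor,
                           double nscale, NumericVector beta0,
                           double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix B(p, L);
  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = beta0[j];

  // residual r = y - X beta
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) eta += X(i, j) * beta[j];
    r[i] = y[i] - eta;
  }
  // d_j = (1/nscale) sum_i w_i x_ij^2
  std::vector<double> d(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
    d[j] = s / nscale;
  }

  std::vector<bool> active(p, true);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int j = 0; j < p; ++j) active[j] = true;
    bool full_pass = true;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (!full_pass && !active[j]) continue;
        if (d[j] <= 0.0) { beta[j] = 0.0; continue; }
        // g = (1/nscale) sum_i w_i x_ij r_i + d_j beta_j
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * r[i];
        double g = s / nscale + d[j] * beta[j];
        double bj = soft(g, lam * alpha * penalty_factor[j]) /
                    (d[j] + lam * (1.0 - alpha) * penalty_factor[j]);
        double diff = bj - beta[j];
        if (diff != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * diff;
          beta[j] = bj;
          double del = std::fabs(diff) * std::sqrt(d[j]);
          if (del > max_delta) max_delta = del;
        }
        active[j] = (beta[j] != 0.0);
      }
      if (max_delta < tol) {
        if (full_pass) break;
        full_pass = true;       // converged on active set: one clean-up pass
      } else {
        full_pass = false;      // keep cycling the active set
      }
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}
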