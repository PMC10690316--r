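#include <Rcpp.h>
using namespace Rcpp;

// Binomial cooperative-learning path solver: penalized IRLS where every
// weighted working-response problem is the augmented least-squares system
// (top block = observations incl. an explicit unpenalized intercept
// column; remaining rows = the +/- sqrt(rho) agreement blocks with
// response 0 and weight 1). Coordinate descent with warm starts along the
// lambda path and active-set cycling, all in one call to avoid R-level
// overhead in cross-validation loops.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".coop_binom_path")]]
NumericMatrix coop_binom_path(const NumericMatrix& X, const NumericVector& y,
                              const NumericVector& lambda, double alpha,
                              const NumericVector& penalty_factor, int nobs,
                              double tol, int max_sweeps,
                              double irls_tol, int irls_max) {
  const int N = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix B(p, L);
  std::vector<double> beta(p, 0.0);
  // null-model intercept (column 0 is the intercept indicator)
  double ybar = 0.0;
  for (int i = 0; i < nobs; ++i) ybar += y[i];
  ybar /= nobs;
  beta[0] = std::log(ybar / (1.0 - ybar));

  std::vector<double> w(N, 1.0), r(N, 0.0), z(nobs), d(p);
  std::vector<bool> active(p, true);

  // eta over all rows (augmentation rows included: intercept column is 0
  // there, so their "eta" is just the agreement contrast)
  std::vector<double> eta(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int irls = 0; irls < irls_max; ++irls) {
      // working response and weights on the observation block
      for (int i = 0; i < nobs; ++i) {
        const double mu = 1.0 / (1.0 + std::exp(-eta[i]));
        double wi = mu * (1.0 - mu);
        if (wi < 1e-5) wi = 1e-5;
        w[i] = wi;
        z[i] = eta[i] + (y[i] - mu) / wi;
        r[i] = z[i] - eta[i];
      }
      for (int i = nobs; i < N; ++i) r[i] = -eta[i]; // response 0
      // weighted curvature per coordinate
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += w[i] * X(i, j) * X(i, j);
        d[j] = s / nobs;
      }
      std::vector<double> beta_old(beta);
      for (int j = 0; j < p; ++j) active[j] = true;
      bool full_pass = true;
      for (int sweep = 0; sweep < max_sweeps; ++sweep) {
        double max_delta = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!full_pass && !active[j]) continue;
          if (d[j] <= 0.0) { beta[j] = 0.0; continue; }
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += w[i] * X(i, j) * r[i];
          const double g = s / nobs + d[j] * beta[j];
          const double bj = soft(g, lam * alpha * penalty_factor[j]) /
                            (d[j] + lam * (1.0 - alpha) * penalty_factor[j]);
          const double diff = bj - beta[j];
          if (diff != 0.0) {
            for (int i = 0; i < N; ++i) r[i] -= X(i, j) * diff;
            beta[j] = bj;
            const double del = std::fabs(diff) * std::sqrt(d[j]);
            if (del > max_delta) max_delta = del;
          }
          active[j] = (beta[j] != 0.0);
        }
        if (max_delta < tol) {
          if (full_pass) break;
          full_pass = true;
        } else full_pass = false;
      }
      // refresh eta from the coefficient change
      double irls_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = beta[j] - beta_old[j];
        if (diff != 0.0) {
          for (int i = 0; i < N; ++i) eta[i] += X(i, j) * diff;
          const double del = std::fabs(diff);
          if (del > irls_delta) irls_delta = del;
        }
      }
      if (irls_delta < irls_tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}
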