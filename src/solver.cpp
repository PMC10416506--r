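#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

inline double clamp_prob(double p) {
  if (p < 1e-9) return 1e-9;
  if (p > 1.0 - 1e-9) return 1.0 - 1e-9;
  return p;
}

// L1-penalized logistic regression along a decreasing lambda path.
//
// Minimizes  -loglik(b0, b)/N + lambda * ||b||_1  with an unpenalized
// intercept, by iteratively reweighted least squares with cyclic
// coordinate descent on the working quadratic (the glmnet scheme), warm
// starting each path point at the previous solution.  Rows carry case
// weights `cw` (counts of collapsed duplicate rows); N = sum(cw).  The
// first path point at lambda >= lambda_max stays at the exact null
// solution (b = 0, b0 = logit(weighted mean of y)) because the KKT
// condition holds there.
//
// Returns per path point: intercept, slopes, unpenalized log-likelihood,
// outer iteration count, convergence flag and worst KKT violation.
// [[Rcpp::export(rng = false)]]
List cd_logistic_path(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& cw, const NumericVector& lambda,
                      double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix beta(p, L);
  NumericVector beta0(L), loglik(L), kkt(L);
  IntegerVector niter(L);
  LogicalVector conv(L);

  double N = 0.0, ybar = 0.0;
  for (int i = 0; i < n; ++i) { N += cw[i]; ybar += cw[i] * y[i]; }
  ybar /= N;
  double b0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> b(p, 0.0);
  std::vector<double> eta(n, b0);

  const double inner_tol = tol * 0.1;
  const int max_inner = 1000;

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool ok = false;
    const int q = p + 1;  // coordinates: intercept + p slopes
    for (; it < max_iter; ++it) {
      // quadratic approximation at current eta; w = cw * p(1-p),
      // working response z = eta + (y - p)/wobs
      std::vector<double> w(n), z(n);
      for (int i = 0; i < n; ++i) {
        double pi = clamp_prob(1.0 / (1.0 + std::exp(-eta[i])));
        double wobs = pi * (1.0 - pi);
        if (wobs < 1e-9) wobs = 1e-9;
        w[i] = cw[i] * wobs;
        z[i] = eta[i] + (y[i] - pi) / wobs;
      }
      // precompute the Gram system for U = [1, X]: A = U'WU, r = U'Wz
      // (covariance mode: each CD sweep is then O(p^2))
      std::vector<double> A(q * q, 0.0), r(q, 0.0), coef(q);
      coef[0] = b0;
      for (int j = 0; j < p; ++j) coef[j + 1] = b[j];
      for (int i = 0; i < n; ++i) {
        double wi = w[i];
        A[0] += wi;
        r[0] += wi * z[i];
        for (int j = 0; j < p; ++j) {
          double xj = X(i, j);
          if (xj == 0.0) continue;
          double wx = wi * xj;
          A[j + 1] += wx;                  // row 0 (intercept) cross term
          r[j + 1] += wx * z[i];
          for (int k = j; k < p; ++k) {
            double xk = X(i, k);
            if (xk != 0.0) A[(j + 1) * q + (k + 1)] += wx * xk;
          }
        }
      }
      for (int j = 0; j < q; ++j)
        for (int k = 0; k < j; ++k)
          A[j * q + k] = A[k * q + j];
      // coordinate descent on the quadratic
      double outer_delta = 0.0;
      for (int inner = 0; inner < max_inner; ++inner) {
        double maxd = 0.0;
        for (int j = 0; j < q; ++j) {
          double ajj = A[j * q + j];
          if (ajj <= 0.0) continue;
          double g = r[j];
          const double* Aj = &A[j * q];
          for (int k = 0; k < q; ++k)
            if (k != j) g -= Aj[k] * coef[k];
          double cj_new = (j == 0)
            ? g / ajj
            : soft_threshold(g / N, lam) / (ajj / N);
          double d = cj_new - coef[j];
          if (d != 0.0) {
            coef[j] = cj_new;
            if (std::fabs(d) > maxd) maxd = std::fabs(d);
          }
        }
        if (maxd > outer_delta) outer_delta = maxd;
        if (maxd < inner_tol) break;
      }
      b0 = coef[0];
      for (int j = 0; j < p; ++j) b[j] = coef[j + 1];
      // refresh eta from the updated parameters
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) if (b[j] != 0.0) e += X(i, j) * b[j];
        eta[i] = e;
      }
      if (outer_delta < tol) { ok = true; ++it; break; }
    }
    // Clip numerically-zero slopes: a coefficient sitting exactly on the
    // KKT boundary (e.g. at lambda_max) can come out as ~1e-16 through
    // floating-point summation-order noise; treating it as nonzero would
    // corrupt the model-size count EBIC depends on.
    for (int j = 0; j < p; ++j) {
      if (b[j] != 0.0 && std::fabs(b[j]) < 1e-10) {
        b[j] = 0.0;
        for (int i = 0; i < n; ++i) {
          double e = b0;
          for (int jj = 0; jj < p; ++jj)
            if (b[jj] != 0.0) e += X(i, jj) * b[jj];
          eta[i] = e;
        }
      }
    }
    // unpenalized log-likelihood and KKT violation at the solution
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      ll += cw[i] * (y[i] * eta[i] - std::log1p(std::exp(eta[i])));
    std::vector<double> grad(p, 0.0);
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      double d = cw[i] * (pi - y[i]);
      for (int j = 0; j < p; ++j) grad[j] += d * X(i, j);
    }
    double worst = 0.0;
    for (int j = 0; j < p; ++j) {
      double g = grad[j] / N, v;
      if (b[j] > 0.0)      v = std::fabs(g + lam);
      else if (b[j] < 0.0) v = std::fabs(g - lam);
      else                 v = std::max(0.0, std::fabs(g) - lam);
      if (v > worst) worst = v;
    }
    beta0[l] = b0;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
    loglik[l] = ll;
    niter[l] = it;
    conv[l] = ok;
    kkt[l] = worst;
  }

  return List::create(_["intercept"] = beta0, _["beta"] = beta,
                      _["loglik"] = loglik, _["niter"] = niter,
                      _["converged"] = conv, _["kkt"] = kkt);
}

// Single-site Gibbs sampler for the {0,1} Ising model
// P(x) propto exp(sum_i tau_i x_i + sum_{i<j} omega_ij x_i x_j).
// One retained row per `thin` full sweeps after `burnin` sweeps.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_ising(const NumericVector& tau,
                                 const NumericMatrix& omega,
                                 int n, int burnin, int thin) {
  const int p = tau.size();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int j = 0; j < p; ++j) {
    double pj = 1.0 / (1.0 + std::exp(-tau[j]));
    x[j] = (R::unif_rand() < pj) ? 1 : 0;
  }
  auto sweep = [&]() {
    for (int j = 0; j < p; ++j) {
      double e = tau[j];
      for (int k = 0; k < p; ++k)
        if (k != j && x[k]) e += omega(j, k);
      double pj = 1.0 / (1.0 + std::exp(-e));
      x[j] = (R::unif_rand() < pj) ? 1 : 0;
    }
  };
  for (int s = 0; s < burnin; ++s) sweep();
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < thin; ++s) sweep();
    for (int j = 0; j < p; ++j) out(i, j) = x[j];
  }
  return out;
}
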