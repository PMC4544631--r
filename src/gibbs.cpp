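#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static const int INC1 = 1;

// x'e over a marker column (BLAS ddot keeps the reduction off the scalar
// dependency chain, which dominates the sampler's cost otherwise)
static inline double col_dot(const double* col, const double* e, int n) {
  return F77_CALL(ddot)(const_cast<int*>(&n), const_cast<double*>(col),
                        const_cast<int*>(&INC1), const_cast<double*>(e),
                        const_cast<int*>(&INC1));
}

static inline void col_axpy(double a, const double* col, double* e, int n) {
  F77_CALL(daxpy)(const_cast<int*>(&n), &a, const_cast<double*>(col),
                  const_cast<int*>(&INC1), e, const_cast<int*>(&INC1));
}

// Inverse-Gaussian(mu, lambda) via Michael-Schucany-Haas; uses R's RNG so
// draws are reproducible under set.seed().
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Scaled-inverse-chi^2 draw: (ss + S) / chisq(df). S and df follow the
// convention of the BLR/BGLR samplers (S acts as a prior sum of squares).
static double rscaled_inv_chisq(double ss, double S, double df) {
  return (ss + S) / R::rchisq(df);
}

// Gibbs sampler for Bayesian ridge regression:
//   y = 1*mu + X beta + e,  beta_j ~ N(0, sigma2_b) (common variance),
//   sigma2_b ~ scaled-inv-chi2(S_beta, df_beta),
//   sigma2_e ~ scaled-inv-chi2(S_eps, df_eps).
// Scalar per-marker updates with residual bookkeeping.
// [[Rcpp::export]]
List brr_gibbs_cpp(NumericMatrix X, NumericVector y, int n_iter, int burn_in,
                   int thin, double S_eps, double df_eps, double S_beta,
                   double df_beta) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = Rcpp::mean(y);
  std::vector<double> beta(p, 0.0), e(n);
  double ss0 = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = y[i] - mu; ss0 += e[i] * e[i]; }
  double vary = ss0 / (n > 1 ? n - 1 : 1);
  double sigma2_e = vary * 0.5 + 1e-8;
  // start the common effect variance at a 50/50 variance partition so the
  // chain does not have to climb out of a near-zero shrinkage state
  double sum_colvar = 0.0;
  int p_eff = 0;  // monomorphic columns carry no likelihood information
  for (int j = 0; j < p; ++j) {
    sum_colvar += xtx[j] / n;
    if (xtx[j] > 0.0) ++p_eff;
  }
  double sigma2_b = (sum_colvar > 0.0 ? vary * 0.5 / sum_colvar : 1.0) + 1e-8;

  // posterior means are Rao-Blackwellized: the conditional mean rhs/c is
  // accumulated instead of the draw, cutting Monte-Carlo error sharply
  std::vector<double> beta_mean(p, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0, s2b_mean = 0.0;
  int n_samp = 0;

  for (int it = 1; it <= n_iter; ++it) {
    bool keep = it > burn_in && ((it - burn_in) % thin == 0);
    // intercept
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i] + mu;
    double mu_new = esum / n + norm_rand() * std::sqrt(sigma2_e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // marker effects
    double lambda = sigma2_e / sigma2_b;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] == 0.0) { beta[j] = 0.0; continue; }
      const double* xj = &X(0, j);
      double rhs = xtx[j] * beta[j] + col_dot(xj, e.data(), n);
      double c = xtx[j] + lambda;
      double bnew = rhs / c + norm_rand() * std::sqrt(sigma2_e / c);
      double d = bnew - beta[j];
      if (d != 0.0) col_axpy(-d, xj, e.data(), n);
      beta[j] = bnew;
      if (keep) beta_mean[j] += rhs / c;
    }
    // variances
    double ssb = 0.0;
    for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
    sigma2_b = rscaled_inv_chisq(ssb, S_beta, p_eff + df_beta);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = rscaled_inv_chisq(sse, S_eps, n + df_eps);

    if (keep) {
      ++n_samp;
      mu_mean += mu; s2e_mean += sigma2_e; s2b_mean += sigma2_b;
    }
  }
  for (int j = 0; j < p; ++j) beta_mean[j] /= n_samp;
  return List::create(_["mu"] = mu_mean / n_samp,
                      _["beta"] = NumericVector(beta_mean.begin(), beta_mean.end()),
                      _["sigma2_e"] = s2e_mean / n_samp,
                      _["sigma2_beta"] = s2b_mean / n_samp,
                      _["n_samples"] = n_samp);
}

// Gibbs sampler for the Bayesian LASSO (Park & Casella parameterization):
//   beta_j ~ N(0, sigma2_e * tau2_j), tau2_j ~ Exp(lambda2 / 2),
//   lambda2 ~ Gamma(shape_r, rate_delta),
//   sigma2_e ~ scaled-inv-chi2(S_eps, df_eps).
// [[Rcpp::export]]
List bl_gibbs_cpp(NumericMatrix X, NumericVector y, int n_iter, int burn_in,
                  int thin, double S_eps, double df_eps, double lambda2_init,
                  double shape_r, double rate_delta) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = Rcpp::mean(y);
  std::vector<double> beta(p, 0.0), tau2(p, 1.0), e(n);
  double ss0 = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = y[i] - mu; ss0 += e[i] * e[i]; }
  double sigma2_e = ss0 / n * 0.5 + 1e-8;
  int p_eff = 0;  // monomorphic columns are excluded from every count
  for (int j = 0; j < p; ++j) if (xtx[j] > 0.0) ++p_eff;
  double lambda2 = lambda2_init;
  for (int j = 0; j < p; ++j) tau2[j] = 2.0 / lambda2;

  std::vector<double> beta_mean(p, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0, l2_mean = 0.0;
  int n_samp = 0;

  for (int it = 1; it <= n_iter; ++it) {
    bool keep = it > burn_in && ((it - burn_in) % thin == 0);
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i] + mu;
    double mu_new = esum / n + norm_rand() * std::sqrt(sigma2_e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xtx[j] == 0.0) { beta[j] = 0.0; continue; }
      const double* xj = &X(0, j);
      double rhs = xtx[j] * beta[j] + col_dot(xj, e.data(), n);
      double c = xtx[j] + 1.0 / tau2[j];
      double bnew = rhs / c + norm_rand() * std::sqrt(sigma2_e / c);
      double d = bnew - beta[j];
      if (d != 0.0) col_axpy(-d, xj, e.data(), n);
      beta[j] = bnew;
      if (keep) beta_mean[j] += rhs / c;  // Rao-Blackwellized mean
    }
    // tau2_j | rest: 1/tau2_j ~ InvGaussian(sqrt(lambda2 sigma2_e / beta_j^2), lambda2)
    double sum_tau2 = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] == 0.0) continue;
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-14) b2 = 1e-14;
      double m = std::sqrt(lambda2 * sigma2_e / b2);
      double inv = rinvgauss(m, lambda2);
      tau2[j] = 1.0 / inv;
      sum_tau2 += tau2[j];
    }
    // lambda2 | rest ~ Gamma(shape_r + p_eff, rate_delta + sum(tau2)/2)
    lambda2 = R::rgamma(shape_r + p_eff, 1.0 / (rate_delta + sum_tau2 / 2.0));
    // sigma2_e | rest (beta scaled by sigma2_e enters the SS)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    double ssb = 0.0;
    for (int j = 0; j < p; ++j)
      if (xtx[j] > 0.0) ssb += beta[j] * beta[j] / tau2[j];
    sigma2_e = rscaled_inv_chisq(sse + ssb, S_eps, n + p_eff + df_eps);

    if (keep) {
      ++n_samp;
      mu_mean += mu; s2e_mean += sigma2_e; l2_mean += lambda2;
    }
  }
  for (int j = 0; j < p; ++j) beta_mean[j] /= n_samp;
  return List::create(_["mu"] = mu_mean / n_samp,
                      _["beta"] = NumericVector(beta_mean.begin(), beta_mean.end()),
                      _["sigma2_e"] = s2e_mean / n_samp,
                      _["lambda2"] = l2_mean / n_samp,
                      _["n_samples"] = n_samp);
}
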