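// Single-site Gibbs samplers for whole-genome regression.
//
// Both samplers work on the pre-whitened system: rows of the design
// and the response are divided by sqrt(R_ii) up front (done on the R
// side), turning heterogeneous residual weights into homogeneous
// algebra. The intercept column is then 1/sqrt(R_ii), not 1.
//
// All randomness goes through R's RNG so set.seed() on the R side
// gives bit-identical chains.

#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian draw (Michael, Schucany & Haas).
static double rinvgauss(double mu, double lambda) {
  double z = R::norm_rand();
  double y = z * z;
  double x = mu + 0.5 * mu * mu * y / lambda -
    0.5 * (mu / lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// scaled inverse chi-square draw: (df * scale) / chisq_df
static double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericVector y, NumericMatrix X, NumericVector x0,
                  int n_iter, int burn_in, int thin,
                  double pi_alpha, double pi_beta,
                  double v, double S_a, double S_e,
                  double var_a0, double var_e0, double pi0) {
  const int n = y.size(), m = X.ncol();
  std::vector<double> a(m, 0.0);
  std::vector<int> incl(m, 0);
  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double x0tx0 = 0.0;
  for (int i = 0; i < n; ++i) x0tx0 += x0[i] * x0[i];

  double mu = 0.0, var_a = var_a0, var_e = var_e0, pi = pi0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  const int n_keep = (n_iter - burn_in) / thin;
  std::vector<double> a_mean(m, 0.0), freq(m, 0.0);
  NumericVector var_a_chain(n_keep), var_e_chain(n_keep),
    pi_chain(n_keep), mu_chain(n_keep);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double r0 = 0.0;
    for (int i = 0; i < n; ++i) r0 += x0[i] * e[i];
    r0 += x0tx0 * mu;
    double mu_new = R::rnorm(r0 / x0tx0, std::sqrt(var_e / x0tx0));
    for (int i = 0; i < n; ++i) e[i] -= x0[i] * (mu_new - mu);
    mu = mu_new;

    int k = 0;
    double ssa = 0.0;
    const double log_odds_prior = std::log(pi) - std::log1p(-pi);
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { a[j] = 0.0; incl[j] = 0; continue; }
      const double *xj = &X(0, j);
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += xj[i] * e[i];
      r += xtx[j] * a[j];              // residual with marker j removed
      double Cj = xtx[j] + var_e / var_a;
      double log_bf = 0.5 * std::log(var_e / (var_a * Cj)) +
        0.5 * r * r / (var_e * Cj);
      double lo = log_odds_prior + log_bf;
      double p1 = 1.0 / (1.0 + std::exp(-lo));
      double a_old = a[j];
      if (R::unif_rand() < p1) {
        double a_new = R::rnorm(r / Cj, std::sqrt(var_e / Cj));
        a[j] = a_new; incl[j] = 1;
        ++k; ssa += a_new * a_new;
      } else {
        a[j] = 0.0; incl[j] = 0;
      }
      if (a[j] != a_old) {
        const double d = a[j] - a_old;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * d;
      }
    }

    var_a = rscinvchisq(v + k, (v * S_a + ssa) / (v + k));
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    var_e = rscinvchisq(v + n, (v * S_e + sse) / (v + n));
    pi = R::rbeta(pi_alpha + k, pi_beta + m - k);
    if (pi <= 0.0) pi = 1e-12;
    if (pi >= 1.0) pi = 1.0 - 1e-12;

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        a_mean[j] += a[j];
        freq[j] += incl[j];
      }
      var_a_chain[kept] = var_a;
      var_e_chain[kept] = var_e;
      pi_chain[kept] = pi;
      mu_chain[kept] = mu;
      ++kept;
    }
  }
  NumericVector am(m), fr(m);
  for (int j = 0; j < m; ++j) {
    am[j] = a_mean[j] / kept;
    fr[j] = freq[j] / kept;
  }
  return List::create(_["effect_mean"] = am, _["inclusion_freq"] = fr,
                      _["mu_chain"] = mu_chain,
                      _["var_a_chain"] = var_a_chain,
                      _["var_e_chain"] = var_e_chain,
                      _["pi_chain"] = pi_chain, _["n_kept"] = kept);
}

// [[Rcpp::export(name = ".blasso_gibbs")]]
List blasso_gibbs(NumericVector y, NumericMatrix X, NumericVector x0,
                  int n_iter, int burn_in, int thin,
                  double lambda_shape, double lambda_rate,
                  double lambda_max, double var_e0) {
  const int n = y.size(), m = X.ncol();
  std::vector<double> a(m, 0.0), tau2(m, 0.01);
  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double x0tx0 = 0.0;
  for (int i = 0; i < n; ++i) x0tx0 += x0[i] * x0[i];

  double mu = 0.0, var_e = var_e0;
  double lambda2 = 1.0;
  const double lambda2_max = lambda_max * lambda_max;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  const int n_keep = (n_iter - burn_in) / thin;
  std::vector<double> a_mean(m, 0.0);
  NumericVector var_e_chain(n_keep), lambda_chain(n_keep),
    mu_chain(n_keep);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double r0 = 0.0;
    for (int i = 0; i < n; ++i) r0 += x0[i] * e[i];
    r0 += x0tx0 * mu;
    double mu_new = R::rnorm(r0 / x0tx0, std::sqrt(var_e / x0tx0));
    for (int i = 0; i < n; ++i) e[i] -= x0[i] * (mu_new - mu);
    mu = mu_new;

    double sum_tau2 = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { a[j] = 0.0; sum_tau2 += tau2[j]; continue; }
      const double *xj = &X(0, j);
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += xj[i] * e[i];
      r += xtx[j] * a[j];
      double prec = xtx[j] / var_e + 1.0 / tau2[j];
      double mean = (r / var_e) / prec;
      double a_old = a[j];
      double a_new = R::rnorm(mean, std::sqrt(1.0 / prec));
      a[j] = a_new;
      const double d = a_new - a_old;
      for (int i = 0; i < n; ++i) e[i] -= xj[i] * d;
      // 1/tau2 | a, lambda ~ inverse-Gaussian(lambda/|a|, lambda^2)
      double lam = std::sqrt(lambda2);
      double absa = std::fabs(a_new);
      if (absa < 1e-10) absa = 1e-10;
      double inv_tau2 = rinvgauss(lam / absa, lambda2);
      if (inv_tau2 < 1e-12) inv_tau2 = 1e-12;
      tau2[j] = 1.0 / inv_tau2;
      sum_tau2 += tau2[j];
    }

    // lambda^2 | tau2: gamma, truncated so lambda stays below the bound
    for (int tries = 0; tries < 100; ++tries) {
      double cand = R::rgamma(lambda_shape + m,
                              1.0 / (lambda_rate + 0.5 * sum_tau2));
      if (cand > 0.0 && cand < lambda2_max) { lambda2 = cand; break; }
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    // flat prior on var_e
    var_e = sse / R::rchisq(std::max(n - 2, 3));

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) a_mean[j] += a[j];
      var_e_chain[kept] = var_e;
      lambda_chain[kept] = std::sqrt(lambda2);
      mu_chain[kept] = mu;
      ++kept;
    }
  }
  NumericVector am(m);
  for (int j = 0; j < m; ++j) am[j] = a_mean[j] / kept;
  return List::create(_["effect_mean"] = am, _["mu_chain"] = mu_chain,
                      _["var_e_chain"] = var_e_chain,
                      _["lambda_chain"] = lambda_chain,
                      _["n_kept"] = kept);
}
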