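#include <Rcpp.h>
using namespace Rcpp;

// Draw from a scaled inverse chi-square distribution with nu degrees of
// freedom and scale S: nu * S / chisq(nu).
static inline double rscinvchisq(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// BayesB single-site Gibbs sampler.
//
// Model: y = 1*mu + sum_k Z_k beta_k + e, where beta_k = 0 with prior
// probability pi_null and otherwise N(0, sigma2_gk) with a per-locus
// scaled-inverse-chi-square(nu_g, s_g) variance. The inclusion indicator
// is sampled with the effect integrated out (conditional on sigma2_gk);
// the effect, locus variance, mean and residual variance are Gibbs steps.
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List bayesb_mcmc(const NumericMatrix& Z, const NumericVector& y,
                 int n_iter, int burn_in, int thin, double pi_null,
                 double nu_g, double s_g, double nu_e, double s_e) {
  const int n = Z.nrow();
  const int m = Z.ncol();

  std::vector<double> ck(m); // Z_k' Z_k
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    const double* zk = &Z(0, k);
    for (int i = 0; i < n; ++i) s += zk[i] * zk[i];
    ck[k] = s;
  }

  std::vector<double> beta(m, 0.0), sigma_gk(m);
  for (int k = 0; k < m; ++k) sigma_gk[k] = rscinvchisq(nu_g, s_g);

  double mu = Rcpp::mean(y);
  double sigma_e2 = Rcpp::var(y);
  if (sigma_e2 <= 0.0) sigma_e2 = s_e;

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const double log_prior_odds =
      std::log1p(-pi_null) - std::log(pi_null > 0.0 ? pi_null : 1e-300);

  const int n_retained = (n_iter - burn_in) / thin;
  NumericVector beta_sum(m), incl_sum(m);
  NumericVector sigma_e_trace(n_retained);
  double mu_sum = 0.0;
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // overall mean
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += e[i];
    double mu_new = mu + se / n + R::norm_rand() * std::sqrt(sigma_e2 / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // marker sweep
    for (int k = 0; k < m; ++k) {
      const double* zk = &Z(0, k);
      const double bold = beta[k];
      if (ck[k] == 0.0) { // monomorphic column: effect unidentifiable
        beta[k] = 0.0;
        sigma_gk[k] = rscinvchisq(nu_g, s_g);
        continue;
      }
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += zk[i] * e[i];
      r += ck[k] * bold; // Z_k' (e with marker k excluded)

      const double v = sigma_e2 + ck[k] * sigma_gk[k];
      const double log_bf = 0.5 * std::log(sigma_e2 / v) +
          0.5 * r * r * sigma_gk[k] / (sigma_e2 * v);
      const double log_odds = log_prior_odds + log_bf;
      double p1;
      if (log_odds > 35.0) p1 = 1.0;
      else if (log_odds < -35.0) p1 = 0.0;
      else { const double o = std::exp(log_odds); p1 = o / (1.0 + o); }

      double bnew = 0.0;
      if (unif_rand() < p1) {
        const double prec = ck[k] / sigma_e2 + 1.0 / sigma_gk[k];
        const double mean = (r / sigma_e2) / prec;
        bnew = mean + R::norm_rand() / std::sqrt(prec);
        sigma_gk[k] = rscinvchisq(nu_g + 1.0,
                                  (nu_g * s_g + bnew * bnew) / (nu_g + 1.0));
      } else {
        sigma_gk[k] = rscinvchisq(nu_g, s_g);
      }
      if (bnew != bold) {
        const double db = bnew - bold;
        for (int i = 0; i < n; ++i) e[i] -= zk[i] * db;
        beta[k] = bnew;
      }
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = rscinvchisq(nu_e + n, (sse + nu_e * s_e) / (nu_e + n));
    if (!std::isfinite(sigma_e2) || sigma_e2 <= 0.0) {
      stop("BayesB sampler diverged: residual variance became non-finite "
           "at iteration %d (sse = %g)", it, sse);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int k = 0; k < m; ++k) {
        beta_sum[k] += beta[k];
        if (beta[k] != 0.0) incl_sum[k] += 1.0;
      }
      mu_sum += mu;
      sigma_e_trace[stored] = sigma_e2;
      ++stored;
    }
  }

  NumericVector beta_mean(m), incl_prob(m);
  for (int k = 0; k < m; ++k) {
    beta_mean[k] = beta_sum[k] / stored;
    incl_prob[k] = incl_sum[k] / stored;
  }
  return List::create(
      _["mu"] = mu_sum / stored,
      _["gamma"] = beta_mean,
      _["inclusion_prob"] = incl_prob,
      _["n_retained"] = stored,
      _["sigma_e_trace"] = sigma_e_trace);
}
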