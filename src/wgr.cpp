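// Single-site Gibbs samplers for whole-genome regression.
//
// Model: y_i = mu + sum_j x_ij beta_j + e_i, with a spike-and-slab prior
// on beta_j: zero with probability pi, otherwise normal with a common
// variance (BayesC) or a locus-specific variance (BayesB, giving the
// marginal t prior).  Variances carry scaled-inverse-chi-square priors.
// GBLUP is BayesC with pi = 0.  Columns of X are expected mean-centred.
//
// The inclusion indicator is sampled with the effect integrated out; the
// effect, when included, from its normal full conditional.  Per-iteration
// genetic variance is the empirical variance of X beta over the training
// individuals (recovered as y - mu - e, so no extra matrix product).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_wgr_gibbs(NumericVector y, NumericMatrix X, double pi_excl,
                   int chain_length, int burn_in,
                   double nu_b, double S_b, double nu_e, double S_e,
                   bool bayesB, bool fix_var,
                   double sigma_b2_fixed, double sigma_e2_fixed) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  const double* Xp = X.begin();  // column-major
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = Xp + (size_t) j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }
  double ybar = mean(y);
  double mu = ybar;
  std::vector<double> beta(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double sigma_e2 = fix_var ? sigma_e2_fixed : S_e * nu_e / (nu_e - 2.0);
  double sigma_b2 = fix_var ? sigma_b2_fixed : S_b * nu_b / (nu_b - 2.0);
  std::vector<double> sigma_bj2(p, sigma_b2);  // BayesB locus variances
  double log_prior_odds =
    (pi_excl > 0.0) ? std::log((1.0 - pi_excl) / pi_excl) : 0.0;

  std::vector<double> beta_sum(p, 0.0);
  std::vector<int> incl_count(p, 0);
  double mu_sum = 0.0;
  NumericVector sg2_chain(chain_length), se2_chain(chain_length),
                h2m_chain(chain_length), sb2_chain(chain_length);
  int kept = 0;

  for (int it = 0; it < chain_length; ++it) {
    // intercept
    double me = 0.0;
    for (int i = 0; i < n; ++i) me += e[i];
    me /= n;
    double mu_new = me + mu + norm_rand() * std::sqrt(sigma_e2 / n);
    double d = mu - mu_new;
    for (int i = 0; i < n; ++i) e[i] += d;
    mu = mu_new;

    // loci
    for (int j = 0; j < p; ++j) {
      double s2 = bayesB ? sigma_bj2[j] : sigma_b2;
      double bold = beta[j];
      if (xtx[j] <= 0.0) {
        // monomorphic column: no data signal; indicator from the prior
        bool incl = (pi_excl <= 0.0) || (unif_rand() < 1.0 - pi_excl);
        beta[j] = incl ? norm_rand() * std::sqrt(s2) : 0.0;
        if (incl && it >= burn_in) ++incl_count[j];
        continue;
      }
      const double* xj = Xp + (size_t) j * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xtx[j] * bold;
      bool incl;
      if (pi_excl <= 0.0) {
        incl = true;
      } else {
        double c = xtx[j] * s2 + sigma_e2;
        double logBF = -0.5 * std::log(c / sigma_e2) +
                       0.5 * rhs * rhs * s2 / (sigma_e2 * c);
        double lo = log_prior_odds + logBF;
        double prob = 1.0 / (1.0 + std::exp(-lo));
        incl = (unif_rand() < prob);
      }
      double bnew = 0.0;
      if (incl) {
        double lambda = sigma_e2 / s2;
        double v = sigma_e2 / (xtx[j] + lambda);
        bnew = rhs / (xtx[j] + lambda) + norm_rand() * std::sqrt(v);
        if (it >= burn_in) ++incl_count[j];
      }
      if (bnew != bold) {
        double db = bold - bnew;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * db;
      }
      beta[j] = bnew;
    }

    // variances
    if (!fix_var) {
      if (bayesB) {
        for (int j = 0; j < p; ++j) {
          double ss = beta[j] * beta[j];
          if (beta[j] != 0.0)
            sigma_bj2[j] = (ss + nu_b * S_b) / R::rchisq(nu_b + 1.0);
          else
            sigma_bj2[j] = nu_b * S_b / R::rchisq(nu_b);
        }
      } else {
        double ss = 0.0; int m = 0;
        for (int j = 0; j < p; ++j) {
          if (beta[j] != 0.0) { ss += beta[j] * beta[j]; ++m; }
        }
        sigma_b2 = (ss + nu_b * S_b) / R::rchisq(nu_b + m);
      }
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = (sse + nu_e * S_e) / R::rchisq(nu_e + n);
    }

    // genomic variance this iteration: empirical variance of X beta
    double su = 0.0, su2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double u = y[i] - mu - e[i];
      su += u; su2 += u * u;
    }
    double vg = (su2 - su * su / n) / (n - 1.0);
    sg2_chain[it] = vg;
    se2_chain[it] = sigma_e2;
    if (bayesB) {
      double sb = 0.0;
      for (int j = 0; j < p; ++j) sb += sigma_bj2[j];
      sb2_chain[it] = sb / p;
    } else {
      sb2_chain[it] = sigma_b2;
    }
    h2m_chain[it] = vg / (vg + sigma_e2);

    if (it >= burn_in) {
      ++kept;
      mu_sum += mu;
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector bhat(p), mf(p);
  for (int j = 0; j < p; ++j) {
    bhat[j] = beta_sum[j] / kept;
    mf[j] = (double) incl_count[j] / kept;
  }
  return List::create(_["mu"] = mu_sum / kept, _["beta"] = bhat,
                      _["mf"] = mf, _["sigma_g2"] = sg2_chain,
                      _["sigma_e2"] = se2_chain, _["sigma_b2"] = sb2_chain,
                      _["h2m"] = h2m_chain,
                      _["kept"] = kept);
}
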