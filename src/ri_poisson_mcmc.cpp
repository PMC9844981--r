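// Metropolis-within-Gibbs sampler for the Gaussian random-intercept Poisson
// model used by the Bayesian bias analysis:
//   y_ij ~ Poisson(mu_ij),  log mu_ij = x_ij' beta + b_i,
//   beta_k ~ N(0, coef_variance),  b_i ~ N(0, tau),
//   1/tau ~ Gamma(precision_shape, precision_rate).
// Coefficients and random intercepts move by random-walk Metropolis with
// step sizes adapted during burn-in only (frozen afterwards so the kernel
// satisfies detailed balance); the precision is a conjugate Gibbs draw.
// Uses R's RNG throughout so chains are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// Poisson working log-likelihood contribution, constants dropped.
static inline double loglik_term(double y, double eta) {
  return y * eta - std::exp(eta);
}

// [[Rcpp::export(name = ".ri_poisson_chain")]]
List ri_poisson_chain(NumericMatrix X, NumericVector y, IntegerVector cluster,
                      int n_cluster, int n_burnin, int n_keep,
                      double coef_variance, double precision_shape,
                      double precision_rate,
                      NumericVector beta_init, NumericVector b_init,
                      double tau_init,
                      NumericVector beta_scale_init, double b_scale_init,
                      bool adapt, bool update_beta, bool update_b) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta_init);
  NumericVector b = clone(b_init);
  NumericVector beta_scale = clone(beta_scale_init);
  double b_scale = b_scale_init;
  double tau = tau_init;

  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = b[cluster[i] - 1];
    for (int k = 0; k < p; ++k) e += X(i, k) * beta[k];
    eta[i] = e;
  }

  NumericMatrix beta_draws(n_keep, p);
  NumericVector tau_draws(n_keep);
  NumericVector acc_beta(p);
  double acc_b = 0.0;
  std::vector<double> blk_acc_beta(p, 0.0);
  double blk_acc_b = 0.0;
  const int blk = 50;

  std::vector<double> dll(n_cluster), bprop(n_cluster);
  std::vector<int> accept_cl(n_cluster);

  const int n_total = n_burnin + n_keep;
  for (int it = 0; it < n_total; ++it) {
    const bool kept = it >= n_burnin;

    if (update_beta) {
      for (int k = 0; k < p; ++k) {
        double prop = beta[k] + beta_scale[k] * R::norm_rand();
        double diff = prop - beta[k];
        double dl = 0.0;
        for (int i = 0; i < n; ++i) {
          double e2 = eta[i] + X(i, k) * diff;
          dl += loglik_term(y[i], e2) - loglik_term(y[i], eta[i]);
        }
        dl += -0.5 * (prop * prop - beta[k] * beta[k]) / coef_variance;
        if (std::log(R::unif_rand()) < dl) {
          for (int i = 0; i < n; ++i) eta[i] += X(i, k) * diff;
          beta[k] = prop;
          blk_acc_beta[k] += 1.0;
          if (kept) acc_beta[k] += 1.0;
        }
      }
    }

    if (update_b) {
      for (int c = 0; c < n_cluster; ++c) {
        bprop[c] = b[c] + b_scale * R::norm_rand();
        dll[c] = 0.0;
      }
      for (int i = 0; i < n; ++i) {
        int c = cluster[i] - 1;
        double e2 = eta[i] + (bprop[c] - b[c]);
        dll[c] += loglik_term(y[i], e2) - loglik_term(y[i], eta[i]);
      }
      double acc_now = 0.0;
      for (int c = 0; c < n_cluster; ++c) {
        double dl = dll[c] -
          0.5 * (bprop[c] * bprop[c] - b[c] * b[c]) / tau;
        accept_cl[c] = std::log(R::unif_rand()) < dl;
        if (accept_cl[c]) acc_now += 1.0;
      }
      for (int i = 0; i < n; ++i) {
        int c = cluster[i] - 1;
        if (accept_cl[c]) eta[i] += bprop[c] - b[c];
      }
      for (int c = 0; c < n_cluster; ++c)
        if (accept_cl[c]) b[c] = bprop[c];
      blk_acc_b += acc_now / n_cluster;
      if (kept) acc_b += acc_now / n_cluster;
    }

    // Gibbs step for the precision 1/tau: the full conditional given the
    // random intercepts is Gamma(shape + n_cluster/2, rate + sum(b^2)/2).
    double ss = 0.0;
    for (int c = 0; c < n_cluster; ++c) ss += b[c] * b[c];
    double prec = R::rgamma(precision_shape + 0.5 * n_cluster,
                            1.0 / (precision_rate + 0.5 * ss));
    tau = 1.0 / prec;

    if (adapt && !kept && ((it + 1) % blk == 0)) {
      for (int k = 0; k < p; ++k) {
        double rate = blk_acc_beta[k] / blk;
        beta_scale[k] *= std::exp(rate - 0.44);
        blk_acc_beta[k] = 0.0;
      }
      double rate_b = blk_acc_b / blk;
      b_scale *= std::exp(rate_b - 0.44);
      blk_acc_b = 0.0;
    }

    if (kept) {
      int row = it - n_burnin;
      for (int k = 0; k < p; ++k) beta_draws(row, k) = beta[k];
      tau_draws[row] = tau;
    }
  }

  return List::create(
    _["beta"] = beta_draws,
    _["tau"] = tau_draws,
    _["accept_beta"] = n_keep > 0 ? acc_beta / n_keep : acc_beta,
    _["accept_b"] = n_keep > 0 ? acc_b / n_keep : acc_b,
    _["state"] = List::create(
      _["beta"] = beta, _["b"] = b, _["tau"] = tau,
      _["beta_scale"] = beta_scale, _["b_scale"] = b_scale));
}
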