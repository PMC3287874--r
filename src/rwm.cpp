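// Random-walk Metropolis core for the logistic-coefficient posterior.
// Uses R's RNG (norm_rand / unif_rand) so chains are reproducible via
// set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bernoulli log-likelihood, overflow-safe for |eta| up to ~700
static double loglik(const arma::mat& X, const arma::vec& y,
                     const arma::vec& beta) {
  arma::vec eta = X * beta;
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i), l1pe;
    if (e <= 18.0)      l1pe = std::log1p(std::exp(e));
    else if (e <= 33.3) l1pe = e + std::exp(-e);
    else                l1pe = e;
    ll += y(i) * e - l1pe;
  }
  return ll;
}

// [[Rcpp::export]]
List rwm_chain_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::vec& init, const arma::mat& prop_L,
                   double scale0, int n_burnin, int n_draws,
                   double prior_bound, bool adapt, double target_accept,
                   int thin) {
  const int p = X.n_cols;
  arma::vec beta = init;
  double ll = loglik(X, y, beta);
  double lscale = std::log(scale0);
  arma::mat draws(n_draws, p);
  arma::vec devs(n_draws);
  int acc_keep = 0, acc_burn = 0, n_keep_it = 0;
  int batch_n = 0, batch_acc = 0, batch_id = 0;
  const int total = n_burnin + n_draws * thin;
  arma::vec z(p);
  for (int t = 0; t < total; ++t) {
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    arma::vec prop = beta + std::exp(lscale) * (prop_L * z);
    bool accepted = false;
    if (arma::all(arma::abs(prop) <= prior_bound)) {
      double llp = loglik(X, y, prop);
      if (std::log(unif_rand()) < llp - ll) {
        beta = prop; ll = llp; accepted = true;
      }
    }
    if (t < n_burnin) {
      if (accepted) ++acc_burn;
      if (adapt) {            // scale-only adaptation, frozen after burn-in
        ++batch_n; if (accepted) ++batch_acc;
        if (batch_n == 50) {
          ++batch_id;
          double rate = batch_acc / 50.0;
          double delta = std::min(0.5, 1.0 / std::sqrt((double)batch_id));
          lscale += (rate > target_accept ? delta : -delta);
          batch_n = 0; batch_acc = 0;
        }
      }
    } else {
      if (accepted) ++acc_keep;
      ++n_keep_it;
      int k = t - n_burnin;
      if ((k + 1) % thin == 0) {
        draws.row(k / thin) = beta.t();
        devs(k / thin) = -2.0 * ll;
      }
    }
  }
  return List::create(
    _["draws"] = draws,
    _["deviances"] = devs,
    _["acceptance_rate"] = n_keep_it > 0 ? (double)acc_keep / n_keep_it : NA_REAL,
    _["burnin_acceptance_rate"] = n_burnin > 0 ? (double)acc_burn / n_burnin : NA_REAL,
    _["final_scale"] = std::exp(lscale));
}
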