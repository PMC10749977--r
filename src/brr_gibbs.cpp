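#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gibbs sampler for Bayesian ridge regression:
//   y = mu + Z beta + e,  beta_j ~ N(0, s2b),  e ~ N(0, s2e I)
// with scaled-inverse-chi-square hyperpriors on s2b and s2e. Marker effects
// are updated one at a time against the running residual (the standard
// single-site scheme, O(n) per marker). Uses R's RNG so set.seed() in R
// fixes the chain.
// [[Rcpp::export(name = ".brr_gibbs")]]
List brr_gibbs_cpp(const arma::vec& y, const arma::mat& Z,
                   int n_iter, int burn_in, int thin,
                   double df_b, double S_b, double df_e, double S_e,
                   bool fix_variances, double s2b0, double s2e0,
                   bool include_mu) {
  RNGScope scope;
  const int n = Z.n_rows, p = Z.n_cols;
  arma::vec z2(p);
  for (int j = 0; j < p; ++j) z2(j) = arma::dot(Z.col(j), Z.col(j));

  double mu = include_mu ? arma::mean(y) : 0.0;
  arma::vec beta(p, arma::fill::zeros);
  double s2b = fix_variances ? s2b0 : std::max(1e-8, S_b);
  double s2e = fix_variances ? s2e0 : std::max(1e-8, S_e);

  arma::vec e = y - mu; // residual, beta = 0 initially

  arma::vec beta_mean(p, arma::fill::zeros);
  double mu_mean = 0.0, s2b_mean = 0.0, s2e_mean = 0.0;
  int n_kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    if (include_mu) {
      // residual without mu
      double rbar = arma::mean(e) + mu;
      double mu_new = R::rnorm(rbar, std::sqrt(s2e / n));
      e += mu - mu_new;
      mu = mu_new;
    }
    double lambda = s2e / s2b;
    for (int j = 0; j < p; ++j) {
      double bj = beta(j);
      if (z2(j) <= 0.0) { beta(j) = R::rnorm(0.0, std::sqrt(s2b)); continue; }
      // rhs against residual with marker j removed
      double rhs = arma::dot(Z.col(j), e) + z2(j) * bj;
      double cj = z2(j) + lambda;
      double bnew = R::rnorm(rhs / cj, std::sqrt(s2e / cj));
      e += Z.col(j) * (bj - bnew);
      beta(j) = bnew;
    }
    if (!fix_variances) {
      double bb = arma::dot(beta, beta);
      s2b = (S_b * df_b + bb) / R::rchisq(df_b + p);
      double ee = arma::dot(e, e);
      s2e = (S_e * df_e + ee) / R::rchisq(df_e + n);
    }
    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      beta_mean += beta;
      mu_mean += mu; s2b_mean += s2b; s2e_mean += s2e;
      ++n_kept;
    }
  }
  if (n_kept > 0) {
    beta_mean /= n_kept; mu_mean /= n_kept;
    s2b_mean /= n_kept; s2e_mean /= n_kept;
  }
  return List::create(_["beta"] = beta_mean, _["mu"] = mu_mean,
                      _["sigma2_b"] = s2b_mean, _["sigma2_e"] = s2e_mean,
                      _["n_samples"] = n_kept);
}
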