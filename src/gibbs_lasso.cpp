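// Gibbs sampler for linear regression with independent Laplace (double
// exponential) priors on the slopes, using the exponential scale-mixture
// representation: beta_j | omega_j ~ N(0, omega_j), omega_j ~ Exp(tau^2/2)
// marginalizes to Laplace(0, rate tau). The intercept has a vague normal
// prior (precision `beta0_prec`) and sigma a uniform prior on
// (sigma_lo, sigma_hi). All randomness comes from R's RNG so runs are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// inverse-Gaussian draw (Michael, Schucany & Haas)
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (!(x > 0.0)) x = 1e-12;
  double z = unif_rand();
  if (z <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// truncated draw of sigma from p(sigma) ~ sigma^{-n} exp(-ss/(2 sigma^2))
// restricted to (lo, hi); inverse-gamma proposal on sigma^2 with rejection,
// clamped to the nearer bound if the region is never hit
static double draw_sigma(double ss, int n, double lo, double hi) {
  double shape = (n - 1.0) / 2.0;
  if (shape <= 0.0) shape = 0.5;
  for (int t = 0; t < 200; ++t) {
    double g = R::rgamma(shape, 2.0 / std::max(ss, 1e-300));
    double s2 = 1.0 / std::max(g, 1e-300);
    double s = std::sqrt(s2);
    if (s > lo && s < hi) return s;
  }
  double mode = std::sqrt(ss / std::max(n + 1.0, 2.0));
  return std::min(std::max(mode, lo * 1.000001), hi * 0.999999);
}

// [[Rcpp::export]]
List gibbs_blasso_cpp(const arma::mat& X, const arma::vec& y, double tau,
                      int n_iter, int burnin, int n_chains,
                      double beta0_prec, double sigma_lo, double sigma_hi) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const arma::mat XtX = X.t() * X;
  const double ybar = arma::mean(y);
  double ysd = arma::stddev(y);
  if (!(ysd > 0.0)) ysd = 1.0;

  List chains(n_chains);
  for (int ch = 0; ch < n_chains; ++ch) {
    arma::vec beta(p, arma::fill::zeros);
    arma::vec omega(p, arma::fill::ones);
    // overdispersed starts across chains
    double beta0 = ybar + ysd * norm_rand() * 0.5;
    double sigma = ysd * std::exp(0.5 * norm_rand());
    if (sigma <= sigma_lo) sigma = sigma_lo * 1.01;
    if (sigma >= sigma_hi) sigma = sigma_hi * 0.99;

    int keep = n_iter - burnin;
    arma::mat draws(keep, p + 2);
    for (int it = 0; it < n_iter; ++it) {
      double s2 = sigma * sigma;

      // slopes: multivariate normal full conditional
      arma::mat A = XtX / s2;
      A.diag() += 1.0 / omega;
      arma::vec b = X.t() * (y - beta0) / s2;
      arma::mat R = arma::chol(A); // upper
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), b));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z(j) = norm_rand();
      beta = mu + arma::solve(arma::trimatu(R), z);

      // intercept
      double v = 1.0 / (n / s2 + beta0_prec);
      arma::vec resid0 = y - X * beta;
      double m = v * arma::accu(resid0) / s2;
      beta0 = m + std::sqrt(v) * norm_rand();

      // latent scales
      for (int j = 0; j < p; ++j) {
        double bj = std::fabs(beta(j));
        if (bj < 1e-10) bj = 1e-10;
        double inv = rinvgauss1(tau / bj, tau * tau);
        double w = 1.0 / std::max(inv, 1e-12);
        if (w > 1e12) w = 1e12;
        omega(j) = w;
      }

      // residual scale
      arma::vec resid = resid0 - beta0;
      double ss = arma::dot(resid, resid);
      sigma = draw_sigma(ss, n, sigma_lo, sigma_hi);

      if (it >= burnin) {
        int r = it - burnin;
        draws(r, 0) = beta0;
        for (int j = 0; j < p; ++j) draws(r, j + 1) = beta(j);
        draws(r, p + 1) = sigma;
      }
    }
    chains[ch] = draws;
  }
  return chains;
}

// [[Rcpp::export]]
List gibbs_vague_lm_cpp(const arma::mat& X, const arma::vec& y,
                        double coef_prec, int n_iter, int burnin,
                        int n_chains, double sigma_lo, double sigma_hi) {
  // Bayesian linear model with vague independent normal priors (precision
  // `coef_prec`) on all coefficients (X includes the intercept column) and
  // uniform prior on sigma. Used by the stage-2 trait-interaction model.
  const int n = X.n_rows;
  const int p = X.n_cols;
  const arma::mat XtX = X.t() * X;
  const arma::vec Xty = X.t() * y;
  double ysd = arma::stddev(y);
  if (!(ysd > 0.0)) ysd = 1.0;

  List chains(n_chains);
  for (int ch = 0; ch < n_chains; ++ch) {
    double sigma = ysd * std::exp(0.5 * norm_rand());
    if (sigma <= sigma_lo) sigma = sigma_lo * 1.01;
    if (sigma >= sigma_hi) sigma = sigma_hi * 0.99;
    arma::vec theta(p, arma::fill::zeros);

    int keep = n_iter - burnin;
    arma::mat draws(keep, p + 1);
    for (int it = 0; it < n_iter; ++it) {
      double s2 = sigma * sigma;
      arma::mat A = XtX / s2;
      A.diag() += coef_prec;
      arma::mat R = arma::chol(A);
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), Xty / s2));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z(j) = norm_rand();
      theta = mu + arma::solve(arma::trimatu(R), z);

      arma::vec resid = y - X * theta;
      double ss = arma::dot(resid, resid);
      sigma = draw_sigma(ss, n, sigma_lo, sigma_hi);

      if (it >= burnin) {
        int r = it - burnin;
        for (int j = 0; j < p; ++j) draws(r, j) = theta(j);
        draws(r, p) = sigma;
      }
    }
    chains[ch] = draws;
  }
  return chains;
}
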