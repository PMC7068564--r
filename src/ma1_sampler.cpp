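// Metropolis-within-Gibbs sampler for the Gaussian linear model with MA(1)
// residual autocorrelation:
//
//   y_t = x_t' beta + eps_t,   eps_t = eta_t + theta * eta_{t-1},
//
// with eta iid N(0, sigma^2) and the recursion reset at each block boundary
// (eta_{-1} = 0 at the start of every block). Conditional on theta the model
// is linear-Gaussian after the innovation transform z_t = v_t - theta
// z_{t-1}, so beta has a conjugate normal draw; theta (uniform on (-1, 1))
// and log sigma (half-t prior on sigma) are updated by random-walk
// Metropolis steps whose scales adapt during warmup only.
//
// All randomness comes from R's RNG, so set.seed() in R makes a chain
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// innovation transform: z = L(theta)^{-1} v with block resets
static void ma1_transform(const arma::vec& v, const arma::ivec& block,
                          double theta, arma::vec& z) {
  const arma::uword n = v.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    if (i > 0 && block[i] == block[i - 1]) {
      z[i] = v[i] - theta * z[i - 1];
    } else {
      z[i] = v[i];
    }
  }
}

static double sse_given(const arma::vec& resid, const arma::ivec& block,
                        double theta, arma::vec& work) {
  ma1_transform(resid, block, theta, work);
  return arma::dot(work, work);
}

// log of the (unnormalised) half-Student-t density, df nu, scale s
static double log_half_t(double sigma, double nu, double s) {
  return -0.5 * (nu + 1.0) * std::log1p((sigma / s) * (sigma / s) / nu);
}

// [[Rcpp::export]]
List ma1_gibbs_chain(const arma::vec& y, const arma::mat& X,
                     const arma::ivec& block, const arma::vec& prior_sd,
                     double sigma_scale, double sigma_df,
                     int iter, int warmup,
                     double theta_rw, double lsigma_rw,
                     bool fix_theta, double theta_init, double sigma_init) {
  const arma::uword n = y.n_elem, p = X.n_cols;
  if (iter <= warmup) stop("iter must exceed warmup");

  arma::vec beta(p, arma::fill::zeros);
  double theta = fix_theta ? 0.0 : theta_init;
  double lsigma = std::log(sigma_init);

  arma::mat Xt(n, p);
  arma::vec yt(n), work(n), resid(n);
  arma::vec prior_prec = 1.0 / arma::square(prior_sd);

  const int keep = iter - warmup;
  arma::mat draws(keep, p + 2);
  int acc_theta = 0, acc_lsigma = 0;
  double th_rw = theta_rw, ls_rw = lsigma_rw;

  for (int it = 0; it < iter; ++it) {
    double sigma = std::exp(lsigma);
    double sigma2 = sigma * sigma;

    // --- beta | theta, sigma: conjugate normal draw on transformed data
    for (arma::uword j = 0; j < p; ++j) {
      ma1_transform(X.col(j), block, theta, work);
      Xt.col(j) = work;
    }
    ma1_transform(y, block, theta, yt);
    arma::mat A = Xt.t() * Xt / sigma2;
    A.diag() += prior_prec;
    arma::vec b = Xt.t() * yt / sigma2;
    arma::mat R = arma::chol(A);           // A = R'R
    arma::vec mu = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), b));
    arma::vec zn(p);
    for (arma::uword j = 0; j < p; ++j) zn[j] = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(R), zn);

    resid = y - X * beta;

    // --- theta | beta, sigma: random-walk Metropolis on (-1, 1)
    double sse = sse_given(resid, block, theta, work);
    if (!fix_theta) {
      double prop = theta + th_rw * R::norm_rand();
      bool accepted = false;
      if (std::abs(prop) < 1.0) {
        double sse_p = sse_given(resid, block, prop, work);
        double lr = (sse - sse_p) / (2.0 * sigma2);
        if (std::log(R::unif_rand()) < lr) {
          theta = prop;
          sse = sse_p;
          accepted = true;
        }
      }
      if (accepted) ++acc_theta;
      if (it < warmup && (it + 1) % 50 == 0) {
        double rate = acc_theta / double(it + 1);
        th_rw *= std::exp(0.5 * (rate - 0.44));
        th_rw = std::min(std::max(th_rw, 1e-3), 1.0);
      }
    }

    // --- log sigma | beta, theta: random-walk Metropolis
    {
      double prop = lsigma + ls_rw * R::norm_rand();
      double sig_p = std::exp(prop);
      double lp_cur = -double(n) * lsigma - sse / (2.0 * sigma2)
        + log_half_t(sigma, sigma_df, sigma_scale) + lsigma;
      double lp_prop = -double(n) * prop - sse / (2.0 * sig_p * sig_p)
        + log_half_t(sig_p, sigma_df, sigma_scale) + prop;
      if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
        lsigma = prop;
        ++acc_lsigma;
      }
      if (it < warmup && (it + 1) % 50 == 0) {
        double rate = acc_lsigma / double(it + 1);
        ls_rw *= std::exp(0.5 * (rate - 0.44));
        ls_rw = std::min(std::max(ls_rw, 1e-3), 2.0);
      }
    }

    if (it >= warmup) {
      int r = it - warmup;
      for (arma::uword j = 0; j < p; ++j) draws(r, j) = beta[j];
      draws(r, p) = theta;
      draws(r, p + 1) = std::exp(lsigma);
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept_theta"] = acc_theta / double(iter),
    _["accept_lsigma"] = acc_lsigma / double(iter)
  );
}
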