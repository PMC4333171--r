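// Gibbs sampler for the Bayesian LASSO with the double-exponential prior in
// its scale-mixture-of-normals representation:
//   y = mu + X beta + e,  e ~ N(0, I sigma2)
//   beta_j | tau2_j, sigma2 ~ N(0, tau2_j sigma2)
//   tau2_j | lambda2 ~ Exp(lambda2 / 2)
//   sigma2 ~ scaled-inv-chisq(df, S)   (density propto s^-(df/2+1) e^{-S/2s})
//   lambda2 ~ Gamma(shape a1, rate a2)
// Full conditionals: beta_j Gaussian, 1/tau2_j inverse-Gaussian, sigma2
// scaled-inv-chisq, lambda2 Gamma(p + a1, sum(tau2)/2 + a2).
// Uses R's RNG so results are governed by set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double rinvgauss(double mu, double lambda) {
  double v = R::norm_rand();
  double y = v * v;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".blGibbs")]]
Rcpp::List blGibbs(const arma::vec& y, const arma::mat& X,
                   int nIter, int burnIn, int thin,
                   double S, double df, double a1, double a2,
                   double fixTau2, double fixSigma2, double fixLambda2) {
  const int n = y.n_elem, p = X.n_cols;
  vec xtx = sum(square(X), 0).t();

  double mu = mean(y);
  vec beta(p, fill::zeros);
  vec tau2(p);
  tau2.fill(fixTau2 > 0 ? fixTau2 : 1.0);
  double sigma2 = fixSigma2 > 0 ? fixSigma2 : var(y) / 2.0 + 1e-8;
  double lambda2 = fixLambda2 > 0 ? fixLambda2 : 1.0;

  vec e = y - mu;            // residual given current state
  vec betaSum(p, fill::zeros), betaSq(p, fill::zeros);
  double muSum = 0;
  int nKept = 0;

  const int nSamp = (nIter - burnIn + thin - 1) / thin;
  mat samples(nSamp, 4);     // mu, sigma2, lambda2, logPost
  int row = 0;

  for (int it = 0; it < nIter; ++it) {
    // intercept
    double rbar = mean(e) + mu;
    double muNew = R::rnorm(rbar, std::sqrt(sigma2 / n));
    e -= (muNew - mu);
    mu = muNew;

    // marker effects
    for (int j = 0; j < p; ++j) {
      double rj = dot(X.col(j), e) + xtx[j] * beta[j];
      double prec = xtx[j] + 1.0 / tau2[j];
      double m = rj / prec;
      double bNew = R::rnorm(m, std::sqrt(sigma2 / prec));
      if (bNew != beta[j]) {
        e -= X.col(j) * (bNew - beta[j]);
        beta[j] = bNew;
      }
    }

    // scale mixture variances
    if (fixTau2 <= 0) {
      for (int j = 0; j < p; ++j) {
        double b2 = std::max(beta[j] * beta[j], 1e-20);
        double m = std::sqrt(lambda2 * sigma2 / b2);
        tau2[j] = 1.0 / rinvgauss(m, lambda2);
      }
    }

    // residual variance
    if (fixSigma2 <= 0) {
      double ssq = dot(e, e) + dot(square(beta), 1.0 / tau2) + S;
      sigma2 = ssq / R::rchisq(n + p + df);
    }

    // regularization parameter
    if (fixLambda2 <= 0 && fixTau2 <= 0) {
      lambda2 = R::rgamma(p + a1, 1.0 / (accu(tau2) / 2.0 + a2));
    }

    if (!beta.is_finite() || !std::isfinite(sigma2))
      Rcpp::stop("divergent chain at iteration %d", it + 1);

    if (it >= burnIn) {
      betaSum += beta;
      betaSq += square(beta);
      muSum += mu;
      ++nKept;
      if ((it - burnIn) % thin == 0 && row < nSamp) {
        // joint log density up to a constant, for trend monitoring
        double lp = -0.5 * n * std::log(sigma2) - dot(e, e) / (2 * sigma2);
        for (int j = 0; j < p; ++j) {
          lp += -0.5 * std::log(tau2[j] * sigma2) -
                beta[j] * beta[j] / (2 * tau2[j] * sigma2);
          lp += std::log(lambda2 / 2.0) - lambda2 * tau2[j] / 2.0;
        }
        lp += -(df / 2.0 + 1.0) * std::log(sigma2) - S / (2.0 * sigma2);
        lp += (a1 - 1.0) * std::log(lambda2) - a2 * lambda2;
        samples(row, 0) = mu;
        samples(row, 1) = sigma2;
        samples(row, 2) = lambda2;
        samples(row, 3) = lp;
        ++row;
      }
    }
  }

  vec bMean = betaSum / nKept;
  vec bVar = betaSq / nKept - square(bMean);
  bVar.transform([](double v) { return v > 0 ? v : 0.0; });
  return Rcpp::List::create(
      Rcpp::Named("betaMean") = bMean,
      Rcpp::Named("betaSD") = sqrt(bVar),
      Rcpp::Named("muMean") = muSum / nKept,
      Rcpp::Named("samples") = samples.rows(0, row > 0 ? row - 1 : 0));
}
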