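// Hot loop of PCD training and sampling: alternating Gibbs sweeps over a
// batch of chains. Numerics mirror the R reference samplers exactly
// (log-space branch masses, tail-stable inverse-CDF truncated Gaussians);
// randomness comes from R's global RNG stream so seeded runs stay
// deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_drelu_unit(double I, double gp, double gm,
                                       double tp, double tm) {
  const double bp = I - tp, bm = -(I - tm);
  const double sp = std::sqrt(gp), sm = std::sqrt(gm);
  const double logzp = bp * bp / (2.0 * gp) + 0.5 * std::log(2.0 * M_PI / gp) +
    R::pnorm(bp / sp, 0.0, 1.0, 1, 1);
  const double logzm = bm * bm / (2.0 * gm) + 0.5 * std::log(2.0 * M_PI / gm) +
    R::pnorm(bm / sm, 0.0, 1.0, 1, 1);
  const double p_plus = 1.0 / (1.0 + std::exp(logzm - logzp));
  const bool pos = unif_rand() < p_plus;
  const double b = pos ? bp : bm;
  const double s = pos ? sp : sm;
  const double gam = pos ? gp : gm;
  const double alpha = -b / s;
  const double u = std::max(unif_rand(), 1e-300);
  const double z = R::qnorm(std::log(u) + R::pnorm(alpha, 0.0, 1.0, 0, 1),
                            0.0, 1.0, 0, 1);
  const double h = b / gam + z / s;
  return pos ? h : -h;
}

// [[Rcpp::export]]
List cpp_gibbs_sweeps(arma::mat v, const arma::mat& W, const arma::vec& g,
                      const arma::vec& gp, const arma::vec& gm,
                      const arma::vec& tp, const arma::vec& tm,
                      const int n_steps) {
  const arma::uword B = v.n_rows, N = v.n_cols, M = W.n_cols;
  arma::mat h(B, M, arma::fill::zeros);
  for (int s = 0; s < n_steps; ++s) {
    arma::mat I = v * W;
    for (arma::uword m = 0; m < M; ++m)
      for (arma::uword b = 0; b < B; ++b)
        h(b, m) = sample_drelu_unit(I(b, m), gp[m], gm[m], tp[m], tm[m]);
    arma::mat A = h * W.t();
    A.each_row() += g.t();
    for (arma::uword n = 0; n < N; ++n)
      for (arma::uword b = 0; b < B; ++b)
        v(b, n) = (unif_rand() < 1.0 / (1.0 + std::exp(-A(b, n)))) ? 1.0 : 0.0;
  }
  return List::create(_["v"] = v, _["h"] = h);
}
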