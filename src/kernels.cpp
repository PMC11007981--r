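#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Pseudo-log-likelihood of the two-group z-statistic mixture and its gradient
// in (pi0, sigma). z2 holds squared z-statistics, flattened gene by gene;
// m holds the per-gene group sizes in the same order.
//
// Per gene: D_i = pi0 + (1 - pi0) * (1/m_i) * sum_k r_k,
//   r_k = (1 + s2)^(-1/2) * exp(z_k^2 * s2 / (2 (1 + s2))),  s2 = sigma^2.
// Each gene is shifted by its max log-ratio so the accumulation never
// overflows even for |z| far beyond anything a null model produces.
// [[Rcpp::export(name = ".zreg_obj_grad")]]
NumericVector zreg_obj_grad(NumericVector z2, IntegerVector m,
                            double pi0, double sigma) {
  const double s2 = sigma * sigma;
  const double v = 1.0 + s2;
  const double a = s2 / (2.0 * v);
  const double b = 0.5 * std::log(v);
  double ll = 0.0, dpi = 0.0, dsig = 0.0;
  R_xlen_t pos = 0;
  const R_xlen_t ng = m.size();
  for (R_xlen_t i = 0; i < ng; ++i) {
    const int mi = m[i];
    double M = -std::numeric_limits<double>::infinity();
    for (int k = 0; k < mi; ++k) {
      const double lr = a * z2[pos + k] - b;
      if (lr > M) M = lr;
    }
    double S0 = 0.0, S1 = 0.0;
    for (int k = 0; k < mi; ++k) {
      const double u = z2[pos + k];
      const double e = std::exp(a * u - b - M);
      S0 += e;
      S1 += u * e;
    }
    pos += mi;
    const double E = std::exp(-M);  // may underflow to 0 when signal is huge
    const double Rbar_sh = S0 / mi; // mean ratio, shifted by exp(-M)
    const double D_sh = pi0 * E + (1.0 - pi0) * Rbar_sh;
    ll += M + std::log(D_sh);
    dpi += (E - Rbar_sh) / D_sh;
    dsig += (1.0 - pi0) * (sigma / v) * (S1 / v - S0) / (mi * D_sh);
  }
  return NumericVector::create(ll, dpi, dsig);
}

// Grouped log-mean-exp: per gene log( (1/m_i) sum_k exp(x_k) ), with the
// usual max-shift for stability. Used for gene-level lfdr computations.
// [[Rcpp::export(name = ".group_log_mean_exp")]]
NumericVector group_log_mean_exp(NumericVector x, IntegerVector m) {
  const R_xlen_t ng = m.size();
  NumericVector out(ng);
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < ng; ++i) {
    const int mi = m[i];
    double M = -std::numeric_limits<double>::infinity();
    for (int k = 0; k < mi; ++k)
      if (x[pos + k] > M) M = x[pos + k];
    if (!std::isfinite(M)) {  // all -Inf
      out[i] = M;
      pos += mi;
      continue;
    }
    double S = 0.0;
    for (int k = 0; k < mi; ++k) S += std::exp(x[pos + k] - M);
    out[i] = M + std::log(S / mi);
    pos += mi;
  }
  return out;
}

// Per-(gene,SNP) adaptive Gauss-Hermite pass for the full-data model.
// The marginal alternative density integrates the conditional Gaussian
// likelihood over the Fisher-scale effect t ~ N(0, sigma^2), with
// beta = tanh(t / sqrt(n - 3)). On the t scale the likelihood is
// approximately N(zhat, 1) with zhat the observed Fisher-scaled
// correlation, so the integrand's mass sits near the Gaussian-product
// mode mu* = zhat sigma^2 / (1 + sigma^2) with scale
// s* = sigma / sqrt(1 + sigma^2); nodes are centered and scaled there
// (prior-centered nodes miss the likelihood peak entirely once sigma is
// large). Returns per pair the log of the marginal alternative density
// over the null density and, optionally, the posterior mean of t^2 -
// the EM variance update - from the same pass.
//
// xq: standard GH nodes; lwq: log(w_q) + x_q^2 (so that sum_q
// exp(lwq) f(t_q) * sqrt(2) s* is the adaptive GH rule).
// [[Rcpp::export(name = ".reg_pair_pass")]]
List reg_pair_pass(NumericVector yx, NumericVector xx,
                   NumericVector yyg, NumericVector zhat,
                   double sigma, double n,
                   NumericVector xq, NumericVector lwq, bool want_et2) {
  const R_xlen_t np = yx.size();
  const R_xlen_t nq = xq.size();
  NumericVector rho(np);
  NumericVector et2(want_et2 ? np : 0);
  std::vector<double> bufv(nq), buft(nq);
  const double s2 = sigma * sigma;
  const double vstar = s2 / (1.0 + s2);
  const double sstar = std::sqrt(vstar);
  const double rtn3 = std::sqrt(n - 3.0);
  const double lhalf = 0.5 * std::log(2.0 * vstar);
  const double lpri0 = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  const double ln2 = std::log(2.0);
  for (R_xlen_t p = 0; p < np; ++p) {
    const double yxp = yx[p], xxp = xx[p], yyp = yyg[p];
    const double mu = zhat[p] * vstar;
    double M = -std::numeric_limits<double>::infinity();
    for (R_xlen_t q = 0; q < nq; ++q) {
      const double t = mu + M_SQRT2 * sstar * xq[q];
      const double a = t / rtn3;
      const double aa = std::fabs(a);
      const double e2a = std::exp(-2.0 * aa);       // exp(-2|a|), <= 1
      const double babs = (1.0 - e2a) / (1.0 + e2a); // tanh(|a|)
      const double b = (a >= 0.0) ? babs : -babs;
      const double l1mb2 = -2.0 * (aa + std::log1p(e2a) - ln2); // log(1-b^2)
      double val;
      if (l1mb2 < -700.0) {
        val = -1e300;                                // density underflows
      } else {
        const double omb2 = std::exp(l1mb2);
        val = lwq[q] + lhalf + lpri0 - t * t / (2.0 * s2) -
          (n / 2.0) * l1mb2 -
          (yyp - 2.0 * b * yxp + b * b * xxp) / (2.0 * omb2) + 0.5 * yyp;
      }
      bufv[q] = val;
      buft[q] = t;
      if (val > M) M = val;
    }
    double S = 0.0, St = 0.0;
    for (R_xlen_t q = 0; q < nq; ++q) {
      const double e = std::exp(bufv[q] - M);
      S += e;
      St += buft[q] * buft[q] * e;
    }
    rho[p] = M + std::log(S);
    if (want_et2) et2[p] = St / S;
  }
  return List::create(Named("rho") = rho, Named("et2") = et2);
}
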