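#include <Rcpp.h>
using namespace Rcpp;

// logistic sigmoid with argument clamped to +-700 so exp() cannot overflow
static inline double sgm(double x) {
  if (x > 700.0) x = 700.0;
  if (x < -700.0) x = -700.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List cpp_kalman_filter(NumericVector o, double v, double sigma2,
                       double m0, double w0) {
  int T = o.size();
  NumericVector m(T), w(T), k(T), cov(T), mpre(T);
  double mc = m0, wc = w0;
  for (int t = 0; t < T; ++t) {
    mpre[t] = mc;
    double pv = wc + v;
    double kt = pv / (pv + sigma2);
    double mn = mc + kt * (o[t] - mc);
    double wn = (1.0 - kt) * pv;
    cov[t] = (1.0 - kt) * wc;
    k[t] = kt; m[t] = mn; w[t] = wn;
    mc = mn; wc = wn;
  }
  return List::create(_["m"] = m, _["w"] = w, _["k"] = k,
                      _["autocov"] = cov, _["m_pre"] = mpre);
}

// [[Rcpp::export]]
List cpp_vkf_filter(NumericVector o, double lambda, double v0, double sigma2,
                    double m0, double w0) {
  int T = o.size();
  NumericVector m(T), w(T), v(T), k(T), cov(T), mpre(T);
  double mc = m0, wc = w0, vc = v0;
  for (int t = 0; t < T; ++t) {
    mpre[t] = mc;
    double pv = wc + vc;
    double kt = pv / (pv + sigma2);
    double mn = mc + kt * (o[t] - mc);
    double wn = (1.0 - kt) * pv;
    double cv = (1.0 - kt) * wc;
    double dm = mn - mc;
    double vn = vc + lambda * (dm * dm + wn + wc - 2.0 * cv - vc);
    m[t] = mn; w[t] = wn; v[t] = vn; k[t] = kt; cov[t] = cv;
    mc = mn; wc = wn; vc = vn;
  }
  return List::create(_["m"] = m, _["w"] = w, _["v"] = v, _["k"] = k,
                      _["autocov"] = cov, _["m_pre"] = mpre);
}

// [[Rcpp::export]]
List cpp_bvkf_filter(NumericVector o, double lambda, double v0, double omega,
                     double m0, double w0, bool sd_step = false) {
  int T = o.size();
  NumericVector m(T), w(T), v(T), k(T), alpha(T), cov(T), mpre(T), phat(T);
  double mc = m0, wc = w0, vc = v0;
  for (int t = 0; t < T; ++t) {
    mpre[t] = mc;
    double p = sgm(mc);
    phat[t] = p;
    double pv = wc + vc;
    double kt = pv / (pv + omega);
    double at = sd_step ? std::sqrt(pv) : pv;
    double mn = mc + at * (o[t] - p);
    double wn = (1.0 - kt) * pv;
    double cv = (1.0 - kt) * wc;
    double dm = mn - mc;
    double vn = vc + lambda * (dm * dm + wn + wc - 2.0 * cv - vc);
    m[t] = mn; w[t] = wn; v[t] = vn; k[t] = kt; alpha[t] = at; cov[t] = cv;
    mc = mn; wc = wn; vc = vn;
  }
  return List::create(_["m"] = m, _["w"] = w, _["v"] = v, _["k"] = k,
                      _["alpha"] = alpha, _["autocov"] = cov,
                      _["m_pre"] = mpre, _["p_pre"] = phat);
}

// [[Rcpp::export]]
List cpp_rw_filter(NumericVector o, double alpha, double init) {
  int T = o.size();
  NumericVector m(T), mpre(T);
  double mc = init;
  for (int t = 0; t < T; ++t) {
    mpre[t] = mc;
    mc = mc + alpha * (o[t] - mc);
    m[t] = mc;
  }
  return List::create(_["m"] = m, _["m_pre"] = mpre);
}

// Two-level HGF for continuous observations (variational scheme with a
// second-order Taylor step at the volatility level; Mathys-style updates).
// Numerical failure (non-positive posterior precision at any level) is a
// result state: the trajectory is flagged and frozen at the failing trial.
// [[Rcpp::export]]
List cpp_hgf2_filter(NumericVector o, double nu, double kappa, double omega,
                     double sigma2, double mu2_0, double mu3_0,
                     double s2_0, double s3_0) {
  int T = o.size();
  NumericVector mu2(T, NA_REAL), s2(T, NA_REAL), mu3(T, NA_REAL),
    s3(T, NA_REAL), vol(T, NA_REAL);
  bool valid = true;
  int first_bad = NA_INTEGER;
  double m2 = mu2_0, v2 = s2_0, m3 = mu3_0, v3 = s3_0;
  for (int t = 0; t < T; ++t) {
    double ex = kappa * m3 + omega;
    if (ex > 700.0 || !R_finite(ex)) { valid = false; first_bad = t + 1; break; }
    double q = std::exp(ex);
    double s2hat = v2 + q;
    double pihat2 = 1.0 / s2hat;
    double pi2 = pihat2 + 1.0 / sigma2;
    if (!(pi2 > 0.0) || !R_finite(pi2)) { valid = false; first_bad = t + 1; break; }
    double m2n = m2 + ((1.0 / sigma2) / pi2) * (o[t] - m2);
    double v2n = 1.0 / pi2;
    double w2 = q * pihat2;
    double d2 = (v2n + (m2n - m2) * (m2n - m2)) * pihat2 - 1.0;
    double pihat3 = 1.0 / (v3 + nu);
    double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!(pi3 > 0.0) || !R_finite(pi3)) { valid = false; first_bad = t + 1; break; }
    double v3n = 1.0 / pi3;
    double m3n = m3 + 0.5 * kappa * v3n * w2 * d2;
    if (!R_finite(m3n) || !R_finite(m2n)) { valid = false; first_bad = t + 1; break; }
    mu2[t] = m2n; s2[t] = v2n; mu3[t] = m3n; s3[t] = v3n; vol[t] = q;
    m2 = m2n; v2 = v2n; m3 = m3n; v3 = v3n;
  }
  return List::create(_["mu2"] = mu2, _["s2"] = s2, _["mu3"] = mu3,
                      _["s3"] = s3, _["vol"] = vol, _["valid"] = valid,
                      _["first_bad"] = first_bad);
}

// Three-level HGF for binary observations. `lr` is the coefficient applied
// to the level-1 prediction error when updating the level-2 mean (the
// latent-space learning rate); `vol` is the diffusion variance
// exp(kappa*mu3 + omega) entering the trial's prediction.
// [[Rcpp::export]]
List cpp_hgf3bin_filter(NumericVector o, double nu, double kappa, double omega,
                        double mu2_0, double mu3_0, double s2_0, double s3_0) {
  int T = o.size();
  NumericVector mu2(T, NA_REAL), s2(T, NA_REAL), mu3(T, NA_REAL),
    s3(T, NA_REAL), muhat1(T, NA_REAL), lr(T, NA_REAL), vol(T, NA_REAL);
  bool valid = true;
  int first_bad = NA_INTEGER;
  double m2 = mu2_0, v2 = s2_0, m3 = mu3_0, v3 = s3_0;
  for (int t = 0; t < T; ++t) {
    double ex = kappa * m3 + omega;
    if (ex > 700.0 || !R_finite(ex)) { valid = false; first_bad = t + 1; break; }
    double q = std::exp(ex);
    double mh1 = sgm(m2);
    double s2hat = v2 + q;
    double pihat2 = 1.0 / s2hat;
    double pi2 = pihat2 + mh1 * (1.0 - mh1);
    if (!(pi2 > 0.0) || !R_finite(pi2)) { valid = false; first_bad = t + 1; break; }
    double v2n = 1.0 / pi2;
    double m2n = m2 + v2n * (o[t] - mh1);
    double w2 = q * pihat2;
    double d2 = (v2n + (m2n - m2) * (m2n - m2)) * pihat2 - 1.0;
    double pihat3 = 1.0 / (v3 + nu);
    double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!(pi3 > 0.0) || !R_finite(pi3)) { valid = false; first_bad = t + 1; break; }
    double v3n = 1.0 / pi3;
    double m3n = m3 + 0.5 * kappa * v3n * w2 * d2;
    if (!R_finite(m3n) || !R_finite(m2n)) { valid = false; first_bad = t + 1; break; }
    mu2[t] = m2n; s2[t] = v2n; mu3[t] = m3n; s3[t] = v3n;
    muhat1[t] = mh1; lr[t] = v2n; vol[t] = q;
    m2 = m2n; v2 = v2n; m3 = m3n; v3 = v3n;
  }
  return List::create(_["mu2"] = mu2, _["s2"] = s2, _["mu3"] = mu3,
                      _["s3"] = s3, _["muhat1"] = muhat1, _["lr"] = lr,
                      _["vol"] = vol, _["valid"] = valid,
                      _["first_bad"] = first_bad);
}

// Negative log likelihood of a binary outcome sequence under the binary
// VKF's one-step-ahead prediction s(m_{t-1}). The squared-update feedback
// into the volatility can diverge at large lambda * (w + v); once the
// state leaves floating range the remaining trials are penalized (30 per
// trial) so optimizers are steered back toward the stable region instead
// of stalling on a flat non-finite plateau.
// [[Rcpp::export]]
double cpp_bvkf_nll(NumericVector o, double lambda, double v0, double omega,
                    double m0, double w0) {
  int T = o.size();
  double mc = m0, wc = w0, vc = v0, nll = 0.0;
  const double eps = 1e-12;
  const double pen = 30.0;
  for (int t = 0; t < T; ++t) {
    if (!R_finite(mc) || !R_finite(vc) || !R_finite(wc) ||
        vc > 1e150 || std::fabs(mc) > 1e150)
      return nll + pen * (T - t);
    double p = sgm(mc);
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    nll -= o[t] > 0.5 ? std::log(p) : std::log(1.0 - p);
    double pv = wc + vc;
    double kt = pv / (pv + omega);
    double mn = mc + pv * (o[t] - sgm(mc));
    double wn = (1.0 - kt) * pv;
    double cv = (1.0 - kt) * wc;
    double dm = mn - mc;
    vc = vc + lambda * (dm * dm + wn + wc - 2.0 * cv - vc);
    mc = mn; wc = wn;
  }
  return nll;
}

// Same for the 3-level binary HGF (prediction muhat1). A trajectory that
// fails numerically at trial t is penalized in proportion to the trials it
// could not score (30 per trial, above any achievable per-trial NLL in
// practice), so optimizers are drawn toward parameter regions that stay
// valid longer instead of facing a flat plateau.
// [[Rcpp::export]]
double cpp_hgf3bin_nll(NumericVector o, double nu, double kappa, double omega,
                       double mu2_0, double mu3_0, double s2_0, double s3_0) {
  int T = o.size();
  double m2 = mu2_0, v2 = s2_0, m3 = mu3_0, v3 = s3_0, nll = 0.0;
  const double eps = 1e-12;
  const double pen = 30.0;
  for (int t = 0; t < T; ++t) {
    double ex = kappa * m3 + omega;
    if (ex > 700.0 || !R_finite(ex)) return nll + pen * (T - t);
    double q = std::exp(ex);
    double mh1 = sgm(m2);
    double p = mh1;
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    nll -= o[t] > 0.5 ? std::log(p) : std::log(1.0 - p);
    double pihat2 = 1.0 / (v2 + q);
    double pi2 = pihat2 + mh1 * (1.0 - mh1);
    if (!(pi2 > 0.0) || !R_finite(pi2)) return nll + pen * (T - t);
    double v2n = 1.0 / pi2;
    double m2n = m2 + v2n * (o[t] - mh1);
    double w2 = q * pihat2;
    double d2 = (v2n + (m2n - m2) * (m2n - m2)) * pihat2 - 1.0;
    double pihat3 = 1.0 / (v3 + nu);
    double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!(pi3 > 0.0) || !R_finite(pi3)) return nll + pen * (T - t);
    double v3n = 1.0 / pi3;
    double m3n = m3 + 0.5 * kappa * v3n * w2 * d2;
    if (!R_finite(m3n) || !R_finite(m2n)) return nll + pen * (T - t);
    m2 = m2n; v2 = v2n; m3 = m3n; v3 = v3n;
  }
  return R_finite(nll) ? nll : 1e10;
}

// Negative log likelihood of go/no-go choices across cues: the learner is a
// binary VKF per cue, choices follow a softmax on the one-step-ahead mean.
// `outcomes` and `choices` are parallel lists of 0/1 vectors, one per cue.
// [[Rcpp::export]]
double cpp_gonogo_nll(List outcomes, List choices, double lambda, double v0,
                      double omega, double beta, double m0, double w0,
                      bool sd_step = false) {
  int ncue = outcomes.size();
  double nll = 0.0;
  const double eps = 1e-12;
  const double pen = 30.0;
  for (int c = 0; c < ncue; ++c) {
    NumericVector o = outcomes[c];
    NumericVector a = choices[c];
    int T = o.size();
    double mc = m0, wc = w0, vc = v0;
    for (int t = 0; t < T; ++t) {
      // graded penalty on numerical divergence (see cpp_bvkf_nll)
      if (!R_finite(mc) || !R_finite(vc) || !R_finite(wc) ||
          vc > 1e150 || std::fabs(mc) > 1e150) {
        nll += pen * (T - t);
        break;
      }
      double pa = sgm(beta * mc);
      if (pa < eps) pa = eps;
      if (pa > 1.0 - eps) pa = 1.0 - eps;
      nll -= a[t] > 0.5 ? std::log(pa) : std::log(1.0 - pa);
      double pv = wc + vc;
      double kt = pv / (pv + omega);
      double at = sd_step ? std::sqrt(pv) : pv;
      double mn = mc + at * (o[t] - sgm(mc));
      double wn = (1.0 - kt) * pv;
      double cv = (1.0 - kt) * wc;
      double dm = mn - mc;
      vc = vc + lambda * (dm * dm + wn + wc - 2.0 * cv - vc);
      mc = mn; wc = wn;
    }
  }
  return nll;
}

// Simulate one cue of the self-generated go/no-go protocol: the outcome on
// trial t is Bernoulli(s(m_{t-1})) under the agent's own filter and the
// choice is softmax(beta * m_{t-1}). Uses R's RNG.
// [[Rcpp::export]]
List cpp_simulate_gonogo(int n_trials, double lambda, double v0, double omega,
                         double beta, double m0, double w0,
                         bool sd_step = false) {
  NumericVector o(n_trials), a(n_trials);
  double mc = m0, wc = w0, vc = v0;
  for (int t = 0; t < n_trials; ++t) {
    double p = sgm(mc);
    double ot = unif_rand() < p ? 1.0 : 0.0;
    double pa = sgm(beta * mc);
    a[t] = unif_rand() < pa ? 1.0 : 0.0;
    o[t] = ot;
    double pv = wc + vc;
    double kt = pv / (pv + omega);
    double at = sd_step ? std::sqrt(pv) : pv;
    double mn = mc + at * (ot - p);
    double wn = (1.0 - kt) * pv;
    double cv = (1.0 - kt) * wc;
    double dm = mn - mc;
    vc = vc + lambda * (dm * dm + wn + wc - 2.0 * cv - vc);
    mc = mn; wc = wn;
  }
  return List::create(_["outcome"] = o, _["choice"] = a);
}
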