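#include <Rcpp.h>
using namespace Rcpp;

// Forward-filtering backward-sampling for the dual random-walk model
//
//   state x_t = (mu_t, delta_t), x_t = x_{t-1} + eta_t,
//   eta_t ~ N(0, diag(sig_mu^2, sig_del^2))
//   y1_t = mu_t + e_t,            e_t  ~ N(0, sig_obs^2)   (condition A)
//   y2_t = mu_t + delta_t + e'_t, e'_t ~ N(0, sig_obs^2)   (condition B)
//
// Missing observations (o1/o2 false) contribute no update; the states are
// propagated through the transition only. Observations within a time step are
// processed sequentially (their errors are independent), which avoids 2x2
// inversions in the filter. Draws use R's RNG so results are reproducible
// under set.seed().
//
// [[Rcpp::export]]
NumericMatrix ffbs_draw(NumericVector y1, NumericVector y2,
                        LogicalVector o1, LogicalVector o2,
                        double sig_mu, double sig_del, double sig_obs,
                        double m0, double v0_mu, double v0_del) {
  const int T = y1.size();
  const double q1 = sig_mu * sig_mu, q2 = sig_del * sig_del;
  const double R = sig_obs * sig_obs;

  std::vector<double> m1(T), m2(T), p11(T), p12(T), p22(T);

  // forward filter
  double a1 = m0, a2 = 0.0;           // predicted mean
  double c11 = v0_mu, c12 = 0.0, c22 = v0_del;  // predicted cov
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      a1 = m1[t - 1]; a2 = m2[t - 1];
      c11 = p11[t - 1] + q1; c12 = p12[t - 1]; c22 = p22[t - 1] + q2;
    }
    if (o1[t]) {  // y1 = mu + e, H = (1, 0)
      double S = c11 + R;
      double k1 = c11 / S, k2 = c12 / S;
      double r = y1[t] - a1;
      a1 += k1 * r; a2 += k2 * r;
      // P -= S k k'
      double c11n = c11 - S * k1 * k1;
      double c12n = c12 - S * k1 * k2;
      double c22n = c22 - S * k2 * k2;
      c11 = c11n; c12 = c12n; c22 = c22n;
    }
    if (o2[t]) {  // y2 = mu + delta + e, H = (1, 1)
      double S = c11 + 2.0 * c12 + c22 + R;
      double k1 = (c11 + c12) / S, k2 = (c12 + c22) / S;
      double r = y2[t] - (a1 + a2);
      a1 += k1 * r; a2 += k2 * r;
      double c11n = c11 - S * k1 * k1;
      double c12n = c12 - S * k1 * k2;
      double c22n = c22 - S * k2 * k2;
      c11 = c11n; c12 = c12n; c22 = c22n;
    }
    if (c11 < 0) c11 = 0;
    if (c22 < 0) c22 = 0;
    m1[t] = a1; m2[t] = a2; p11[t] = c11; p12[t] = c12; p22[t] = c22;
  }

  NumericMatrix out(T, 2);
  // sample x_T ~ N(m_T, P_T) via 2x2 Cholesky
  {
    double l11 = std::sqrt(std::max(p11[T - 1], 0.0));
    double l21 = (l11 > 0) ? p12[T - 1] / l11 : 0.0;
    double d22 = p22[T - 1] - l21 * l21;
    double l22 = std::sqrt(std::max(d22, 0.0));
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    out(T - 1, 0) = m1[T - 1] + l11 * z1;
    out(T - 1, 1) = m2[T - 1] + l21 * z1 + l22 * z2;
  }
  // backward: x_t | x_{t+1} ~ N(m_t + J (x_{t+1} - m_t), P_t - J Ppred J')
  for (int t = T - 2; t >= 0; --t) {
    double pp11 = p11[t] + q1, pp12 = p12[t], pp22 = p22[t] + q2;
    double det = pp11 * pp22 - pp12 * pp12;
    double j11, j12, j21, j22;
    if (det <= 1e-300) {
      j11 = j12 = j21 = j22 = 0.0;  // fully deterministic transition
    } else {
      double i11 = pp22 / det, i12 = -pp12 / det, i22 = pp11 / det;
      // J = P_t * Ppred^{-1}
      j11 = p11[t] * i11 + p12[t] * i12;
      j12 = p11[t] * i12 + p12[t] * i22;
      j21 = p12[t] * i11 + p22[t] * i12;
      j22 = p12[t] * i12 + p22[t] * i22;
    }
    double d1 = out(t + 1, 0) - m1[t];
    double d2 = out(t + 1, 1) - m2[t];
    double mm1 = m1[t] + j11 * d1 + j12 * d2;
    double mm2 = m2[t] + j21 * d1 + j22 * d2;
    // V = P_t - J Ppred J'
    double jp11 = j11 * pp11 + j12 * pp12;
    double jp12 = j11 * pp12 + j12 * pp22;
    double jp21 = j21 * pp11 + j22 * pp12;
    double jp22 = j21 * pp12 + j22 * pp22;
    double v11 = p11[t] - (jp11 * j11 + jp12 * j12);
    double v12 = p12[t] - (jp11 * j21 + jp12 * j22);
    double v22 = p22[t] - (jp21 * j21 + jp22 * j22);
    if (v11 < 0) v11 = 0;
    if (v22 < 0) v22 = 0;
    double l11 = std::sqrt(v11);
    double l21 = (l11 > 0) ? v12 / l11 : 0.0;
    double d22v = v22 - l21 * l21;
    double l22 = std::sqrt(std::max(d22v, 0.0));
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    out(t, 0) = mm1 + l11 * z1;
    out(t, 1) = mm2 + l21 * z1 + l22 * z2;
  }
  return out;
}
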