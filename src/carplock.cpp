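#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-algorithm log-likelihood for a 2-state HMM over several
// independent tracks laid out contiguously.
//   logemis: T x 2 log emission densities (step x angle, already combined)
//   psi:     T x 2 switching probabilities (1->2, 2->1); the transition from
//            position t-1 to t uses row t-1 (covariates at the step's start)
//   delta:   n_tracks x 2 initial state distributions
//   track_start, track_len: 1-based start index and length per track
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logemis, NumericMatrix psi,
                          NumericMatrix delta, IntegerVector track_start,
                          IntegerVector track_len) {
  double total = 0.0;
  int ntr = track_start.size();
  for (int tr = 0; tr < ntr; ++tr) {
    int s = track_start[tr] - 1;
    int T = track_len[tr];
    double m = std::max(logemis(s, 0), logemis(s, 1));
    double a1 = delta(tr, 0) * std::exp(logemis(s, 0) - m);
    double a2 = delta(tr, 1) * std::exp(logemis(s, 1) - m);
    double c = a1 + a2;
    if (!(c > 0.0) || !std::isfinite(m)) return R_NegInf;
    total += std::log(c) + m;
    a1 /= c; a2 /= c;
    for (int t = 1; t < T; ++t) {
      int i = s + t;
      double p12 = psi(i - 1, 0), p21 = psi(i - 1, 1);
      double b1 = a1 * (1.0 - p12) + a2 * p21;
      double b2 = a1 * p12 + a2 * (1.0 - p21);
      m = std::max(logemis(i, 0), logemis(i, 1));
      if (!std::isfinite(m)) return R_NegInf;
      b1 *= std::exp(logemis(i, 0) - m);
      b2 *= std::exp(logemis(i, 1) - m);
      c = b1 + b2;
      if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
      total += std::log(c) + m;
      a1 = b1 / c; a2 = b2 / c;
    }
  }
  return total;
}

// Exact-discretization Kalman negative log-likelihood of the integrated
// Ornstein-Uhlenbeck (continuous-time correlated random walk) model, both
// axes sharing (beta, sigma^2, tau^2). State per axis: (position, velocity).
//   dt:  n-1 inter-fix gaps (seconds)
//   obs: n x 2 observed positions (x, y)
// [[Rcpp::export]]
double ctcrw_negloglik_cpp(NumericVector dt, NumericMatrix obs, double beta,
                           double sigma2, double tau2, double init_var) {
  int n = obs.nrow();
  double nll = 0.0;
  for (int ax = 0; ax < 2; ++ax) {
    double mx = obs(0, ax), mv = 0.0;
    double Pxx = init_var, Pxv = 0.0, Pvv = sigma2 / (2.0 * beta);
    for (int i = 0; i < n; ++i) {
      if (i > 0) {
        double D = dt[i - 1];
        double e = std::exp(-beta * D);
        double phi = (1.0 - e) / beta;
        double q11 = sigma2 / (beta * beta) *
          (D - 2.0 * phi + (1.0 - e * e) / (2.0 * beta));
        double q12 = sigma2 / (2.0 * beta * beta) * (1.0 - e) * (1.0 - e);
        double q22 = sigma2 * (1.0 - e * e) / (2.0 * beta);
        double nmx = mx + phi * mv;
        double nmv = e * mv;
        double nPxx = Pxx + 2.0 * phi * Pxv + phi * phi * Pvv + q11;
        double nPxv = e * (Pxv + phi * Pvv) + q12;
        double nPvv = e * e * Pvv + q22;
        mx = nmx; mv = nmv; Pxx = nPxx; Pxv = nPxv; Pvv = nPvv;
      }
      double F = Pxx + tau2;
      if (!(F > 0.0) || !std::isfinite(F)) return R_PosInf;
      double v = obs(i, ax) - mx;
      nll += 0.5 * (std::log(2.0 * M_PI * F) + v * v / F);
      double kx = Pxx / F, kv = Pxv / F;
      mx += kx * v; mv += kv * v;
      double uPxx = Pxx - kx * Pxx;
      double uPxv = Pxv - kx * Pxv;
      double uPvv = Pvv - kv * Pxv;
      Pxx = uPxx; Pxv = uPxv; Pvv = uPvv;
    }
  }
  return nll;
}
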