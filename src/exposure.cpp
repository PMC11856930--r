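#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform grid, clamped at the ends.  The
// causal-inference estimate mapping saturates outside any reasonable
// measurement range, so clamping is exact in the tails.
static inline double interp_uniform(double x, double g0, double inv_dg,
                                    const double* v, int n) {
  double t = (x - g0) * inv_dg;
  if (t <= 0.0) return v[0];
  if (t >= n - 1.0) return v[n - 1];
  int i = (int)t;
  double w = t - i;
  return v[i] * (1.0 - w) + v[i + 1] * w;
}

// Batch simulation of the exposure phase: n_reps independent trajectories of
// n_trials bias updates for each session (adapter SOA).  Standard-exponential
// deviates are supplied by the caller, laid out repetition-fastest within
// trial within session (common random numbers: the fixed deviates are scaled
// by the time constants inside, keeping the result smooth in the parameters).
//
// rule: 1 = causal inference (tab = estimate mapping s_hat(m)),
//       2 = asynchrony-contingent (likelihood of simultaneity x alpha x m),
//       3 = asynchrony-correction (|m| > criterion),
//       4 = causal inference, posterior-weighted variant (tab = P(C=1|m)).
//
// Returns an n_reps x n_sessions matrix of final cumulative shifts.
// [[Rcpp::export(name = ".exposure_batch_cpp")]]
NumericMatrix exposure_batch_cpp(int rule, NumericVector adapter,
                                 double beta_pre, double tau_a, double tau_v,
                                 double alpha, double criterion,
                                 double obs_bias,
                                 NumericVector tab_grid, NumericVector tab_val,
                                 NumericVector ea, NumericVector ev,
                                 int n_reps, int n_trials) {
  const int n_sessions = adapter.size();
  if ((R_xlen_t)ea.size() < (R_xlen_t)n_sessions * n_reps * n_trials ||
      (R_xlen_t)ev.size() < (R_xlen_t)n_sessions * n_reps * n_trials)
    stop("noise vectors shorter than n_sessions * n_reps * n_trials");
  if (rule < 1 || rule > 4) stop("unknown update rule code");
  const double* tv_ = tab_val.begin();
  const int ntab = tab_val.size();
  double g0 = 0.0, inv_dg = 1.0;
  if (rule == 1 || rule == 4) {
    if (ntab < 2) stop("causal-inference rules need a lookup table");
    g0 = tab_grid[0];
    inv_dg = 1.0 / (tab_grid[1] - tab_grid[0]);
  }
  NumericMatrix out(n_reps, n_sessions);
  std::vector<double> delta(n_reps);
  const double inv_peak = 1.0 / (tau_a + tau_v);
  const double* pea = ea.begin();
  const double* pev = ev.begin();
  R_xlen_t idx = 0;
  for (int j = 0; j < n_sessions; ++j) {
    const double base = adapter[j] + beta_pre;
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n_trials; ++i, idx += n_reps) {
      const double* eai = pea + idx;
      const double* evi = pev + idx;
      switch (rule) {
      case 1:
        for (int r = 0; r < n_reps; ++r) {
          const double m = base + delta[r] + tau_a * eai[r] - tau_v * evi[r];
          delta[r] += alpha *
            (interp_uniform(m - obs_bias, g0, inv_dg, tv_, ntab) - m);
        }
        break;
      case 2:
        for (int r = 0; r < n_reps; ++r) {
          const double m = base + delta[r] + tau_a * eai[r] - tau_v * evi[r];
          const double x = m - (beta_pre + delta[r]);
          const double lik = inv_peak *
            (x <= 0.0 ? std::exp(x / tau_v) : std::exp(-x / tau_a));
          delta[r] -= lik * alpha * m;
        }
        break;
      case 3:
        for (int r = 0; r < n_reps; ++r) {
          const double m = base + delta[r] + tau_a * eai[r] - tau_v * evi[r];
          if (std::fabs(m) > criterion) delta[r] -= alpha * m;
        }
        break;
      default:
        for (int r = 0; r < n_reps; ++r) {
          const double m = base + delta[r] + tau_a * eai[r] - tau_v * evi[r];
          delta[r] -= alpha *
            interp_uniform(m - obs_bias, g0, inv_dg, tv_, ntab) * m;
        }
      }
    }
    for (int r = 0; r < n_reps; ++r) out(r, j) = delta[r];
  }
  return out;
}
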