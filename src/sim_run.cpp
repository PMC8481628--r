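#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fast single-run engine: one forced-GO school term followed by one
// free-choice vacation phase. Mirrors the pure-R reference path
// (run_school_term / run_vacation) expression for expression and consumes
// the same R RNG stream (one uniform per action choice, via R::runif so
// boundary draws are rejected exactly as in R's runif), so both engines are
// bit-identical for a given seed. Variant codes: 0 none, 1 penalty,
// 2 regret, 3 sr_update.

// [[Rcpp::export]]
List sim_run_cpp(int n, double reward, double cost, double gamma, double beta,
                 int school_episodes, int vacation_episodes,
                 bool lr_scheduled, double lr_constant,
                 int variant, double c_p, double penalty_onset,
                 double penalty_ramp, double c_r, double alpha_sr,
                 int max_steps) {
  NumericVector x(n);
  for (int k = 0; k < n; ++k) x[k] = std::pow(gamma, n - 1 - k);

  double w = 0.0;
  NumericMatrix w_school(school_episodes, n);
  for (int m = 1; m <= school_episodes; ++m) {
    double a = lr_scheduled ? 0.5 / (1 + 0.2 * m) : lr_constant;
    for (int k = 0; k < n - 1; ++k) {
      double v_k = w * x[k];
      double v_k1 = w * x[k + 1];
      double delta = -cost + gamma * v_k1 - v_k;
      w = w + a * delta * x[k];
      w_school(m - 1, k) = w;
    }
    double delta = reward - w * x[n - 1];
    w = w + a * delta * x[n - 1];
    w_school(m - 1, n - 1) = w;
  }

  // tabular tracker initialised at the closed-form true values
  NumericVector v_hat(n);
  for (int k = 0; k < n; ++k) {
    int steps_left = n - 1 - k;
    double C = 0.0;
    for (int j = 0; j < steps_left; ++j) C += std::pow(gamma, j);
    C *= cost;
    v_hat[k] = std::pow(gamma, n - 1 - k) * reward - C;
  }

  int E = vacation_episodes;
  IntegerMatrix stay_counts(E, n - 1);
  NumericMatrix gap_approx(E, n - 1), gap_true(E, n - 1), w_vac(E, n);
  std::fill(gap_approx.begin(), gap_approx.end(), NA_REAL);
  std::fill(gap_true.begin(), gap_true.end(), NA_REAL);
  std::fill(w_vac.begin(), w_vac.end(), NA_REAL);
  LogicalVector truncated(E);

  double t_v = 0.0;

  for (int m = 1; m <= E; ++m) {
    double a = lr_scheduled ? 0.5 / (1 + 0.2 * m) : lr_constant;
    int k = 0;  // 0-based; goal is n - 1
    int steps = 0;

    // first-entry gap recording, with the adjustments the variant applies
    // to the selection-time and reported-true STAY values
    auto record_entry = [&](int row, int kk) {
      double sel = 0.0, rep = 0.0;
      if (variant == 1) {
        double p = (t_v - penalty_onset) / penalty_ramp;
        if (p < 0) p = 0;
        sel = rep = p * c_p;
      } else if (variant == 2) {
        rep = c_r;
      }
      double v_k = w * x[kk];
      double v_k1 = w * x[kk + 1];
      gap_approx(row, kk) = (gamma * v_k1 - cost) - (gamma * v_k - sel);
      gap_true(row, kk) =
        (gamma * v_hat[kk + 1] - cost) - (gamma * v_hat[kk] - rep);
    };

    record_entry(m - 1, 0);
    for (;;) {
      double adj_sel = 0.0, adj_rpe = 0.0;
      if (variant == 1) {
        double p = (t_v - penalty_onset) / penalty_ramp;
        if (p < 0) p = 0;
        adj_sel = adj_rpe = p * c_p;
      } else if (variant == 2) {
        adj_rpe = c_r;
      }
      double v_k = w * x[k];
      double v_k1 = w * x[k + 1];
      double q_go = gamma * v_k1 - cost;
      double q_stay = gamma * v_k - adj_sel;
      double z = beta * (q_stay - q_go);
      if (z > 700) z = 700; else if (z < -700) z = -700;
      double p_go = 1.0 / (1.0 + std::exp(z));
      double u = R::runif(0.0, 1.0);
      t_v += 1;
      steps += 1;
      if (u < p_go) {  // GO
        double delta = -cost + gamma * v_k1 - v_k;
        double delta_true = -cost + gamma * v_hat[k + 1] - v_hat[k];
        w = w + a * delta * x[k];
        v_hat[k] = v_hat[k] + a * delta_true;
        if (variant == 3) {
          double delta_sr = gamma * x[k + 1] - x[k];
          x[k] = x[k] + alpha_sr * delta_sr;
        }
        w_vac(m - 1, k) = w;
        k += 1;
        if (k == n - 1) {
          // the terminal update at the goal is a time-step like any other,
          // so the vacation counter advances here too
          double dterm = reward - w * x[n - 1];
          w = w + a * dterm * x[n - 1];
          v_hat[n - 1] = v_hat[n - 1] + a * (reward - v_hat[n - 1]);
          w_vac(m - 1, n - 1) = w;
          t_v += 1;
          break;
        }
        record_entry(m - 1, k);
      } else {  // STAY
        stay_counts(m - 1, k) += 1;
        double delta = gamma * v_k - v_k - adj_rpe;
        double delta_true = gamma * v_hat[k] - v_hat[k] - adj_rpe;
        w = w + a * delta * x[k];
        v_hat[k] = v_hat[k] + a * delta_true;
        if (variant == 3) {
          double delta_sr = gamma * x[k] - x[k];
          x[k] = x[k] + alpha_sr * delta_sr;
        }
      }
      if (steps >= max_steps) {
        truncated[m - 1] = true;
        break;
      }
    }
  }

  return List::create(
    _["w_school"] = w_school, _["stay_counts"] = stay_counts,
    _["gap_approx"] = gap_approx, _["gap_true"] = gap_true,
    _["w_vac"] = w_vac, _["truncated"] = truncated,
    _["w"] = w, _["v_hat"] = v_hat, _["features"] = x);
}
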