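// Closed-loop saccade trial: grouped burst generator with internal
// displacement-integrator feedback, bilateral granular reservoir with
// Purkinje/fastigial readouts, and a second-order eye plant advanced by
// exact zero-order-hold discretization. This mirrors, step for step, the
// reference R engine composed of the exported step functions; the two are
// asserted equal in the test suite.
//
// record_level: 0 = scalar summary only (training inner loop: the
// trapezoidal gaze-error integral and the endpoint), 1 = all scalar
// signal traces, 2 = traces plus the granule activity histories.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double logistic_rate_c(double x, double f_max) {
  return f_max / (1.0 + std::exp(-x));
}

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(List cfg,
                   const arma::mat& w_mf_grc_c, const arma::mat& w_mf_grc_i,
                   const arma::mat& w_rec_c, const arma::mat& w_rec_i,
                   const arma::vec& w_pf_pc_c, const arma::vec& w_pf_pc_i,
                   const arma::vec& z0_c, const arma::vec& z0_i,
                   const arma::mat& Ad, const arma::vec& Bd,
                   double target, double motivation_scale,
                   Nullable<NumericVector> clamp_yc, int record_level) {
  const double A = as<double>(cfg["A"]);
  const double k = as<double>(cfg["k"]);
  const double sigma = as<double>(cfg["sigma"]);
  const double lam = as<double>(cfg["lam"]);
  const double alpha = as<double>(cfg["alpha"]);
  const double rho = as<double>(cfg["rho"]);
  const double tau = as<double>(cfg["tau"]);
  const double r1 = as<double>(cfg["r1"]);
  const double r2 = as<double>(cfg["r2"]);
  const double w_pc_cfn_c = as<double>(cfg["w_pc_cfn_contra"]);
  const double w_pc_cfn_i = as<double>(cfg["w_pc_cfn_ipsi"]);
  const double w_mf_cfn_c = as<double>(cfg["w_mf_cfn_contra"]);
  const double w_mf_cfn_i = as<double>(cfg["w_mf_cfn_ipsi"]);
  const double f_max = as<double>(cfg["f_max"]);
  const double dt = as<double>(cfg["dt"]);
  const double trial_duration = as<double>(cfg["trial_duration"]);
  const double cutoff = as<double>(cfg["cutoff_after_onset"]);
  const double t_on = as<double>(cfg["t_on"]);
  const double v_thresh = as<double>(cfg["onset_speed_threshold"]);

  const int n = (int) std::lround(trial_duration / dt);
  const int ns = n + 1;
  const int N = (int) z0_c.n_elem;
  const double eps = 1e-12;
  const bool rec = record_level >= 1;
  const bool rec_z = record_level >= 2;

  bool clamped = clamp_yc.isNotNull();
  NumericVector clampv;
  if (clamped) {
    clampv = clamp_yc.get();
    if (clampv.size() != ns)
      stop("clamp_yc must cover the full time grid (%d samples)", ns);
  }

  NumericVector time(rec ? ns : 0), u(rec ? ns : 0), D(rec ? ns : 0),
      mft(rec ? ns : 0), mfb(rec ? ns : 0),
      y_pc_c(rec ? ns : 0), y_pc_i(rec ? ns : 0),
      ycfn_c(rec ? ns : 0), ycfn_i(rec ? ns : 0), y_c(rec ? ns : 0),
      theta(rec ? ns : 0), theta_dot(rec ? ns : 0);
  arma::mat z_hist_c, z_hist_i;
  if (rec_z) {
    z_hist_c.set_size(ns, N);
    z_hist_i.set_size(ns, N);
  }

  arma::vec z_c = z0_c, z_i = z0_i;
  double Dcur = 0.0, ucur = 0.0;
  arma::vec x(2, arma::fill::zeros);  // (theta, theta_dot)

  // sample 1: resting state at t = 0
  const double ypc0_c = arma::dot(w_pf_pc_c, z_c);
  const double ypc0_i = arma::dot(w_pf_pc_i, z_i);
  if (rec) {
    time[0] = 0.0;
    y_pc_c[0] = ypc0_c;
    y_pc_i[0] = ypc0_i;
    ycfn_c[0] = -w_pc_cfn_c * ypc0_c;
    ycfn_i[0] = -w_pc_cfn_i * ypc0_i;
    y_c[0] = clamped ? clampv[0]
                     : (r1 * ycfn_c[0] + r2 * ycfn_i[0]);
    mft[0] = lam * target * std::exp(-(t_on * t_on) / (alpha * alpha));
  }
  if (rec_z) {
    z_hist_c.row(0) = z_c.t();
    z_hist_i.row(0) = z_i.t();
  }

  bool onset_seen = false, hold = false;
  double onset_time = NA_REAL;
  double j_time = 0.0, err_prev = std::fabs(target);
  double j_pc_neg = 0.0;  // integral of negative Purkinje-rate excursions
  bool bad = false;

  for (int i = 0; i < n; ++i) {
    const double t_next = (i + 1) * dt;
    if (!hold && onset_seen && t_next >= onset_time + cutoff - eps)
      hold = true;

    // mossy fibers: target channel from the clock, burst channel as the
    // previous step's efference copy (one-step loop delay)
    double mf_t;
    if (hold) {
      mf_t = 0.0;
    } else if (t_next <= t_on) {
      const double d = t_next - t_on;
      mf_t = lam * target * std::exp(-(d * d) / (alpha * alpha));
    } else {
      mf_t = lam * target;
    }
    const double mf_b = hold ? 0.0 : ucur;
    const double m1 = mf_t / (lam * 20.0);
    const double m2 = mf_b / A;

    // granular reservoirs, one Euler step of tau dz/dt = -z + S, rectified
    arma::vec S_c = w_mf_grc_c.col(0) * m1 + w_mf_grc_c.col(1) * m2 -
                    rho * (w_rec_c * z_c);
    arma::vec S_i = w_mf_grc_i.col(0) * m1 + w_mf_grc_i.col(1) * m2 -
                    rho * (w_rec_i * z_i);
    for (int j = 0; j < N; ++j) {
      S_c[j] = logistic_rate_c(S_c[j], f_max);
      S_i[j] = logistic_rate_c(S_i[j], f_max);
    }
    z_c += (dt / tau) * (S_c - z_c);
    z_i += (dt / tau) * (S_i - z_i);
    z_c.clamp(0.0, arma::datum::inf);
    z_i.clamp(0.0, arma::datum::inf);

    // Purkinje and fastigial readouts, net cerebellar correction
    const double ypc_c = arma::dot(w_pf_pc_c, z_c);
    const double ypc_i = arma::dot(w_pf_pc_i, z_i);
    const double yf_c = -w_pc_cfn_c * ypc_c + w_mf_cfn_c * mf_b;
    const double yf_i = -w_pc_cfn_i * ypc_i + w_mf_cfn_i * mf_b;
    const double yc = clamped ? clampv[i + 1] : (r1 * yf_c + r2 * yf_i);

    // burst generator with displacement-integrator feedback; before t_on
    // the omnipause gate keeps the brainstem silent and the eye still
    const bool gated = hold || t_next < t_on - eps;
    const double y_d = gated ? 0.0 : target;
    double unew = 0.0;
    if (!gated) {
      unew = A * motivation_scale *
             (1.0 - std::exp(-(yc + y_d - Dcur) / sigma));
      if (unew < 0.0) unew = 0.0;
    }
    Dcur += k * unew * dt;

    // eye plant (held still while gated or once the switch has fired)
    if (gated) {
      x[1] = 0.0;
    } else {
      x = Ad * x + Bd * unew;
    }

    const double err = std::fabs(target - x[0]);
    j_time += dt * (err_prev + err) / 2.0;
    err_prev = err;
    if (ypc_c < 0.0) j_pc_neg -= dt * ypc_c;
    if (ypc_i < 0.0) j_pc_neg -= dt * ypc_i;
    if (!std::isfinite(x[0]) || !std::isfinite(unew)) {
      bad = true;
      break;
    }

    if (rec) {
      const int s = i + 1;
      time[s] = t_next;
      u[s] = unew;
      D[s] = Dcur;
      mft[s] = mf_t;
      mfb[s] = mf_b;
      y_pc_c[s] = ypc_c;
      y_pc_i[s] = ypc_i;
      ycfn_c[s] = yf_c;
      ycfn_i[s] = yf_i;
      y_c[s] = yc;
      theta[s] = x[0];
      theta_dot[s] = x[1];
    }
    if (rec_z) {
      z_hist_c.row(i + 1) = z_c.t();
      z_hist_i.row(i + 1) = z_i.t();
    }
    ucur = unew;

    if (!onset_seen && !hold && x[1] >= v_thresh) {
      onset_seen = true;
      onset_time = t_next;
    }
  }

  if (bad)
    stop("numerical divergence: non-finite eye position or burst output");

  List out = List::create(
      _["onset_time"] = onset_time,
      _["hold_time"] = onset_seen ? (onset_time + cutoff) : NA_REAL,
      _["degenerate"] = !onset_seen,
      _["j_time"] = j_time,
      _["j_pc_neg"] = j_pc_neg,
      _["theta_end"] = x[0]);
  if (rec) {
    out["time"] = time;
    out["u"] = u;
    out["D"] = D;
    out["mf_target"] = mft;
    out["mf_burst"] = mfb;
    out["y_pc_contra"] = y_pc_c;
    out["y_pc_ipsi"] = y_pc_i;
    out["ycfn_contra"] = ycfn_c;
    out["ycfn_ipsi"] = ycfn_i;
    out["y_c"] = y_c;
    out["theta"] = theta;
    out["theta_dot"] = theta_dot;
  }
  if (rec_z) {
    out["z_contra"] = wrap(z_hist_c);
    out["z_ipsi"] = wrap(z_hist_i);
  }
  return out;
}
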