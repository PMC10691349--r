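#include "mito_model.h"
using namespace Rcpp;

// Metabolic-accounting neuron. ATP relaxes toward a target set by the
// instantaneous consumption rate c(t); ROS relaxes toward a V-shaped
// function of c(t) with its minimum at c_bar. The metabolic signal
// MS = ROS * (ATP - atp_bar) gates spiking through two thresholds:
// MS > theta_ret fires a metabolic spike, theta_fet < MS (with drive)
// permits a synaptic spike, MS < theta_fet blocks everything.

// [[Rcpp::export]]
List accounting_simulate_cpp(NumericVector par, double duration, double dt,
                             IntegerVector input_drive, int record_every,
                             bool spiking_enabled) {
  const double theta_ret = par["theta_ret"], theta_fet = par["theta_fet"],
               refractory = par["refractory"], baseline = par["baseline_cost"],
               q = par["q"], kernel_ms = par["q_kernel_duration"],
               c_bar = par["c_bar"], c_max = par["c_max"],
               tau_atp = par["tau_atp"], tau_ros = par["tau_ros"],
               ros_min = par["ros_min"], v_slope = par["v_slope"];
  const int exponential_kernel = (int)par["exp_kernel"];

  const int n_steps = (int)std::round(duration / dt);
  const int kernel_steps = std::max(1, (int)std::round(kernel_ms / dt));
  const double atp_bar = std::min(1.0, std::max(0.0, 1.0 - c_bar / c_max));
  const double kernel_tau = kernel_ms / 3.0; // exp kernel: ~95% spent

  // extra consumption from spike kernels, accumulated ahead of time
  std::vector<double> extra(n_steps + kernel_steps + 1, 0.0);

  double atp = std::min(1.0, std::max(0.0, 1.0 - baseline / c_max));
  double ros = ros_min + v_slope * std::fabs(baseline - c_bar);
  double refr = 0.0;

  std::vector<double> sp_t;
  std::vector<int> sp_lab; // 1 metabolic, 2 synaptic
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix traces(n_rec, 5);
  int r = 0;

  for (int i = 0; i < n_steps; ++i) {
    const double c = baseline + extra[i];
    const double atp_target = std::min(1.0, std::max(0.0, 1.0 - c / c_max));
    const double ros_target = ros_min + v_slope * std::fabs(c - c_bar);
    const double ms = ros * (atp - atp_bar);

    if (i % record_every == 0 && r < n_rec) {
      traces(r, 0) = i * dt;
      traces(r, 1) = atp; traces(r, 2) = ros; traces(r, 3) = ms;
      traces(r, 4) = c;
      ++r;
    }

    int spike = 0;
    if (spiking_enabled && refr <= 0.0) {
      if (ms > theta_ret) spike = 1;
      else if (input_drive[i] && ms > theta_fet) spike = 2;
    }
    if (spike) {
      sp_t.push_back(i * dt);
      sp_lab.push_back(spike);
      refr = refractory;
      if (exponential_kernel) {
        double norm = 0.0;
        for (int k = 0; k < kernel_steps; ++k)
          norm += std::exp(-k * dt / kernel_tau);
        for (int k = 0; k < kernel_steps; ++k)
          extra[i + 1 + k] += q * std::exp(-k * dt / kernel_tau) / (norm * dt);
      } else {
        const double flux = q / (kernel_steps * dt);
        for (int k = 0; k < kernel_steps; ++k) extra[i + 1 + k] += flux;
      }
    }

    atp += dt * (atp_target - atp) / tau_atp;
    ros += dt * (ros_target - ros) / tau_ros;
    if (refr > 0.0) refr -= dt;
  }

  NumericMatrix tr(r, 5);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < 5; ++j) tr(i, j) = traces(i, j);
  colnames(tr) = CharacterVector::create("time_ms", "atp", "ros", "ms",
                                         "consumption");
  return List::create(_["spike_times"] = wrap(sp_t),
                      _["spike_labels"] = wrap(sp_lab),
                      _["traces"] = tr,
                      _["atp_bar"] = atp_bar);
}

// Same gating logic, but ATP and ROS come from the full respiration ODE
// (pooled ATP read out as cytosolic ATP). init must hold the baseline
// steady state; atp_bar is the steady cytosolic ATP at the ROS-minimising
// consumption rate.
// [[Rcpp::export]]
List accounting_simulate_mito_cpp(NumericVector par, NumericVector mito_par,
                                  NumericVector init, double atp_bar,
                                  double duration, double dt,
                                  IntegerVector input_drive,
                                  int record_every, bool spiking_enabled) {
  const double theta_ret = par["theta_ret"], theta_fet = par["theta_fet"],
               refractory = par["refractory"], baseline = par["baseline_cost"],
               q = par["q"], kernel_ms = par["q_kernel_duration"],
               ca_coupling = par["ca_coupling"];
  const MitoPar mp = mito_unpack(mito_par);

  const int n_steps = (int)std::round(duration / dt);
  const int kernel_steps = std::max(1, (int)std::round(kernel_ms / dt));
  std::vector<double> extra(n_steps + kernel_steps + 1, 0.0);

  double s[6];
  for (int j = 0; j < 6; ++j) s[j] = init[j];
  double refr = 0.0;

  std::vector<double> sp_t;
  std::vector<int> sp_lab;
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix traces(n_rec, 5);
  int r = 0;

  for (int i = 0; i < n_steps; ++i) {
    const double c = baseline + extra[i];
    const double ms = s[5] * (s[4] - atp_bar);

    if (i % record_every == 0 && r < n_rec) {
      traces(r, 0) = i * dt;
      traces(r, 1) = s[4]; traces(r, 2) = s[5]; traces(r, 3) = ms;
      traces(r, 4) = c;
      ++r;
    }

    int spike = 0;
    if (spiking_enabled && refr <= 0.0) {
      if (ms > theta_ret) spike = 1;
      else if (input_drive[i] && ms > theta_fet) spike = 2;
    }
    if (spike) {
      sp_t.push_back(i * dt);
      sp_lab.push_back(spike);
      refr = refractory;
      const double flux = q / (kernel_steps * dt);
      for (int k = 0; k < kernel_steps; ++k) extra[i + 1 + k] += flux;
      s[2] -= ca_coupling;
      if (s[2] < 0.0)
        stop("calcium coupling drove delta_psi below 0 at t = %f ms", i * dt);
    }

    mito_rk4(s, mp, c, dt);
    mito_check_bounds(s, mp, (i + 1) * dt);
    if (refr > 0.0) refr -= dt;
  }

  NumericMatrix tr(r, 5);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < 5; ++j) tr(i, j) = traces(i, j);
  colnames(tr) = CharacterVector::create("time_ms", "atp", "ros", "ms",
                                         "consumption");
  return List::create(_["spike_times"] = wrap(sp_t),
                      _["spike_labels"] = wrap(sp_lab),
                      _["traces"] = tr,
                      _["atp_bar"] = atp_bar);
}
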