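#include <Rcpp.h>
using namespace Rcpp;

// Connor-Stevens Na/K/leak kinetics plus an A-type K+ conductance with
// Boltzmann activation/inactivation. The effective inactivation
// hA_eff = (1 - rho) * hA + rho interpolates between the fully
// inactivating channel (rho = 0) and the non-inactivating, ROS-modified
// channel (rho = 1). Units: mV, ms, mS/cm^2, uA/cm^2; currents are
// returned in pA for the configured membrane area.

struct HHPar {
  double c_m, g_na, g_k, g_a, g_l, e_na, e_k, e_a, e_l;
  double va, ka, tau_a, vha, kha, tau_ha;
  double area_um2, rho;
  int tau_mode; // 0: gate-removal interpolation, 1: slowed inactivation
  double tau_ha_slow;
};

static inline HHPar hh_unpack(const NumericVector &par, double rho) {
  HHPar p;
  p.c_m = par["c_m"];
  p.g_na = par["g_na"]; p.g_k = par["g_k"]; p.g_a = par["g_a"];
  p.g_l = par["g_l"];
  p.e_na = par["e_na"]; p.e_k = par["e_k"]; p.e_a = par["e_a"];
  p.e_l = par["e_l"];
  p.va = par["va"]; p.ka = par["ka"]; p.tau_a = par["tau_a"];
  p.vha = par["vha"]; p.kha = par["kha"]; p.tau_ha = par["tau_ha"];
  p.area_um2 = par["area_um2"];
  p.tau_mode = (int)par["tau_mode"];
  p.tau_ha_slow = par["tau_ha_slow"];
  p.rho = rho;
  return p;
}

struct Rates { double am, bm, ah, bh, an, bn, ainf, hainf, tau_ha_eff; };

static inline Rates hh_rates(double V, const HHPar &p) {
  Rates r;
  // Connor-Stevens (temperature-adjusted) rate functions
  double x = V + 29.7;
  r.am = std::fabs(x) < 1e-7 ? 3.8 : 0.38 * x / (1.0 - std::exp(-x / 10.0));
  r.bm = 15.2 * std::exp(-0.0556 * (V + 54.7));
  r.ah = 0.266 * std::exp(-0.05 * (V + 48.0));
  r.bh = 3.8 / (1.0 + std::exp(-0.1 * (V + 18.0)));
  x = V + 45.7;
  r.an = std::fabs(x) < 1e-7 ? 0.2 : 0.02 * x / (1.0 - std::exp(-0.1 * x));
  r.bn = 0.25 * std::exp(-0.0125 * (V + 55.7));
  r.ainf = 1.0 / (1.0 + std::exp(-(V - p.va) / p.ka));
  r.hainf = 1.0 / (1.0 + std::exp((V - p.vha) / p.kha));
  // slowed-inactivation mode: rho stretches tau_hA toward tau_ha_slow
  r.tau_ha_eff = p.tau_mode == 1
    ? p.tau_ha + p.rho * (p.tau_ha_slow - p.tau_ha)
    : p.tau_ha;
  return r;
}

static inline double hh_ha_eff(double hA, const HHPar &p) {
  return p.tau_mode == 1 ? hA : (1.0 - p.rho) * hA + p.rho;
}

static void hh_check_gates(const double *g, double t) {
  const double eps = 1e-6;
  for (int j = 0; j < 5; ++j)
    if (!R_finite(g[j]) || g[j] < -eps || g[j] > 1.0 + eps)
      stop("gating variable left [0,1] at t = %f ms; reduce dt", t);
}

// state: V, m, h, n, a, hA
static inline void hh_gate_step(double *st, const HHPar &p, double dt) {
  const Rates r = hh_rates(st[0], p);
  st[1] += dt * (r.am * (1.0 - st[1]) - r.bm * st[1]);
  st[2] += dt * (r.ah * (1.0 - st[2]) - r.bh * st[2]);
  st[3] += dt * (r.an * (1.0 - st[3]) - r.bn * st[3]);
  st[4] += dt * (r.ainf - st[4]) / p.tau_a;
  st[5] += dt * (r.hainf - st[5]) / r.tau_ha_eff;
}

static inline void hh_currents(const double *st, const HHPar &p,
                               double *i_out) {
  const double V = st[0];
  const double ha_eff = hh_ha_eff(st[5], p);
  i_out[0] = p.g_na * st[1] * st[1] * st[1] * st[2] * (V - p.e_na);
  i_out[1] = p.g_k * std::pow(st[3], 4) * (V - p.e_k);
  i_out[2] = p.g_a * st[4] * st[4] * st[4] * ha_eff * (V - p.e_a);
  i_out[3] = p.g_l * (V - p.e_l);
}

// [[Rcpp::export]]
NumericVector hh_init_cpp(NumericVector par, double rho, double v0) {
  const HHPar p = hh_unpack(par, rho);
  const Rates r = hh_rates(v0, p);
  return NumericVector::create(v0,
    r.am / (r.am + r.bm), r.ah / (r.ah + r.bh), r.an / (r.an + r.bn),
    r.ainf, r.hainf);
}

// i_inj: per-step injected current in uA/cm^2 (converted in R from pA)
// [[Rcpp::export]]
List hh_current_clamp_cpp(NumericVector par, double rho,
                          NumericVector init, NumericVector i_inj,
                          double dt, int record_every,
                          double spike_threshold, double dedup_ms) {
  const HHPar p = hh_unpack(par, rho);
  const int n_steps = i_inj.size();
  double st[6];
  for (int j = 0; j < 6; ++j) st[j] = init[j];
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 6);
  int r = 0;
  std::vector<double> spikes;
  bool above = st[0] >= spike_threshold;
  double last_spike = -1e18;
  double cur[4];
  // pA per (uA/cm^2) for the configured area
  const double to_pa = p.area_um2 * 1e-8 * 1e6;

  for (int i = 0; i < n_steps; ++i) {
    if (i % record_every == 0 && r < n_rec) {
      hh_currents(st, p, cur);
      out(r, 0) = i * dt; out(r, 1) = st[0];
      out(r, 2) = cur[0] * to_pa; out(r, 3) = cur[1] * to_pa;
      out(r, 4) = cur[2] * to_pa; out(r, 5) = cur[3] * to_pa;
      ++r;
    }
    hh_currents(st, p, cur);
    const double dv = (-cur[0] - cur[1] - cur[2] - cur[3] + i_inj[i]) / p.c_m;
    hh_gate_step(st, p, dt);
    st[0] += dt * dv;
    hh_check_gates(st + 1, (i + 1) * dt);
    if (st[0] >= spike_threshold && !above) {
      const double t = (i + 1) * dt;
      if (t - last_spike >= dedup_ms) {
        spikes.push_back(t);
        last_spike = t;
      }
      above = true;
    } else if (st[0] < spike_threshold) {
      above = false;
    }
  }
  NumericMatrix tr(r, 6);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < 6; ++j) tr(i, j) = out(i, j);
  colnames(tr) = CharacterVector::create("time_ms", "v_mv", "i_na", "i_k",
                                         "i_a", "i_leak");
  return List::create(_["trace"] = tr,
                      _["spike_times"] = wrap(spikes),
                      _["state"] = NumericVector(st, st + 6));
}

// command: per-step clamped voltage (mV); V follows it exactly.
// [[Rcpp::export]]
NumericMatrix hh_voltage_clamp_cpp(NumericVector par, double rho,
                                   NumericVector init,
                                   NumericVector command,
                                   double dt, int record_every) {
  const HHPar p = hh_unpack(par, rho);
  const int n_steps = command.size();
  double st[6];
  for (int j = 0; j < 6; ++j) st[j] = init[j];
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 6);
  int r = 0;
  double cur[4];
  const double to_pa = p.area_um2 * 1e-8 * 1e6;
  for (int i = 0; i < n_steps; ++i) {
    st[0] = command[i];
    if (i % record_every == 0 && r < n_rec) {
      hh_currents(st, p, cur);
      out(r, 0) = i * dt; out(r, 1) = st[0];
      out(r, 2) = cur[0] * to_pa; out(r, 3) = cur[1] * to_pa;
      out(r, 4) = cur[2] * to_pa; out(r, 5) = cur[3] * to_pa;
      ++r;
    }
    hh_gate_step(st, p, dt);
    hh_check_gates(st + 1, (i + 1) * dt);
  }
  NumericMatrix tr(r, 6);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < 6; ++j) tr(i, j) = out(i, j);
  colnames(tr) = CharacterVector::create("time_ms", "v_mv", "i_na", "i_k",
                                         "i_a", "i_leak");
  return tr;
}
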