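#ifndef METASPIKE_MITO_MODEL_H
#define METASPIKE_MITO_MODEL_H

#include <Rcpp.h>

// Shared reduced respiration backbone, used by the standalone mitochondrial
// integrator and by the accounting neuron's full-ODE backend.

struct MitoPar {
  double k_pyr, pyr_max, k_tca, k_etc, n_pump, k_synth, k_ant, k_leak,
         km_use, tau_ros, f_ret, f_fet;
};

static inline double mito_ros_inf(double atp_m, double delta_psi,
                                  double f_ret, double f_fet) {
  double s = atp_m * delta_psi * f_ret +
             (1.0 - atp_m) * (1.0 - delta_psi) * f_fet;
  return s * s * s;
}

static inline void mito_deriv(const double *s, const MitoPar &p, double cons,
                              double *ds) {
  const double pyr = s[0], nadh = s[1], psi = s[2], atp_m = s[3],
               atp_c = s[4], ros = s[5];
  const double f_tca = p.k_tca * pyr * (1.0 - nadh);
  const double f_etc = p.k_etc * nadh * (1.0 - psi);
  const double f_syn = p.k_synth * psi * (1.0 - atp_m);
  const double f_ant = p.k_ant * atp_m * (1.0 - atp_c);
  const double f_use = cons * atp_c / (atp_c + p.km_use);
  ds[0] = p.k_pyr * (p.pyr_max - pyr) - f_tca;
  ds[1] = f_tca - f_etc;
  ds[2] = p.n_pump * f_etc - f_syn - p.k_leak * psi;
  ds[3] = f_syn - f_ant;
  ds[4] = f_ant - f_use;
  ds[5] = (mito_ros_inf(atp_m, psi, p.f_ret, p.f_fet) - ros) / p.tau_ros;
}

static inline void mito_rk4(double *s, const MitoPar &p, double cons,
                            double dt) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  mito_deriv(s, p, cons, k1);
  for (int j = 0; j < 6; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
  mito_deriv(tmp, p, cons, k2);
  for (int j = 0; j < 6; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
  mito_deriv(tmp, p, cons, k3);
  for (int j = 0; j < 6; ++j) tmp[j] = s[j] + dt * k3[j];
  mito_deriv(tmp, p, cons, k4);
  for (int j = 0; j < 6; ++j)
    s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

static inline MitoPar mito_unpack(const Rcpp::NumericVector &par) {
  MitoPar p;
  p.k_pyr = par["k_pyr"];   p.pyr_max = par["pyr_max"];
  p.k_tca = par["k_tca"];   p.k_etc = par["k_etc"];
  p.n_pump = par["n_pump"]; p.k_synth = par["k_synth"];
  p.k_ant = par["k_ant"];   p.k_leak = par["k_leak"];
  p.km_use = par["km_use"]; p.tau_ros = par["tau_ros"];
  p.f_ret = par["f_ret"];   p.f_fet = par["f_fet"];
  return p;
}

static inline void mito_check_bounds(const double *s, const MitoPar &p,
                                     double t) {
  const double eps = 1e-9;
  bool bad = s[0] < -eps || s[0] > p.pyr_max + eps ||
             s[1] < -eps || s[1] > 1.0 + eps ||
             s[2] < -eps || s[2] > 1.0 + eps ||
             s[3] < -eps || s[3] > 1.0 + eps ||
             s[4] < -eps || s[4] > 1.0 + eps ||
             s[5] < -eps;
  for (int j = 0; j < 6; ++j) if (!R_finite(s[j])) bad = true;
  if (bad)
    Rcpp::stop("mitochondrial state left its admissible bounds at "
               "t = %f ms; reduce dt or check parameters", t);
}

#endif
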