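#include "mito_model.h"
using namespace Rcpp;

// Adenine and NAD pools are conserved by representation (adp_m = 1 - atp_m,
// nad = 1 - nadh). All fluxes are mass-action or saturating, so the unit
// hypercube is forward-invariant for admissible parameters; any excursion
// beyond a small round-off tolerance is reported as an integration failure
// rather than clipped.

// [[Rcpp::export]]
NumericMatrix mito_integrate_cpp(NumericVector init, NumericVector par,
                                 NumericVector consumption,
                                 NumericVector psi_kick,
                                 double dt, int record_every) {
  const MitoPar p = mito_unpack(par);
  const int n_steps = consumption.size();
  double s[6];
  for (int j = 0; j < 6; ++j) s[j] = init[j];
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 7);
  int r = 0;
  out(r, 0) = 0.0;
  for (int j = 0; j < 6; ++j) out(r, j + 1) = s[j];
  ++r;
  for (int i = 0; i < n_steps; ++i) {
    if (psi_kick[i] != 0.0) {
      s[2] -= psi_kick[i];
      if (s[2] < 0.0)
        stop("calcium coupling drove delta_psi below 0 at t = %f ms",
             i * dt);
    }
    mito_rk4(s, p, consumption[i], dt);
    mito_check_bounds(s, p, (i + 1) * dt);
    if ((i + 1) % record_every == 0 && r < n_rec) {
      out(r, 0) = (i + 1) * dt;
      for (int j = 0; j < 6; ++j) out(r, j + 1) = s[j];
      ++r;
    }
  }
  NumericMatrix res = out;
  if (r < n_rec) {
    NumericMatrix trimmed(r, 7);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < 7; ++j) trimmed(i, j) = out(i, j);
    res = trimmed;
  }
  colnames(res) = CharacterVector::create(
    "time_ms", "pyr", "nadh", "delta_psi", "atp_m", "atp_c", "ros");
  return res;
}

// Integrate at constant consumption until the max |derivative| falls below
// tol (checked periodically), or give up after t_max.
// [[Rcpp::export]]
List mito_steady_cpp(NumericVector init, NumericVector par,
                     double consumption, double dt, double t_max,
                     double tol) {
  const MitoPar p = mito_unpack(par);
  double s[6], ds[6];
  for (int j = 0; j < 6; ++j) s[j] = init[j];
  const int n_steps = (int)std::ceil(t_max / dt);
  const int check_every = 500;
  double resid = R_PosInf;
  for (int i = 0; i < n_steps; ++i) {
    mito_rk4(s, p, consumption, dt);
    if ((i + 1) % check_every == 0) {
      mito_check_bounds(s, p, (i + 1) * dt);
      mito_deriv(s, p, consumption, ds);
      resid = 0.0;
      for (int j = 0; j < 6; ++j) resid = std::max(resid, std::fabs(ds[j]));
      if (resid < tol)
        return List::create(_["state"] = NumericVector(s, s + 6),
                            _["residual"] = resid,
                            _["converged"] = true,
                            _["t_elapsed"] = (i + 1) * dt);
    }
  }
  mito_deriv(s, p, consumption, ds);
  resid = 0.0;
  for (int j = 0; j < 6; ++j) resid = std::max(resid, std::fabs(ds[j]));
  return List::create(_["state"] = NumericVector(s, s + 6),
                      _["residual"] = resid,
                      _["converged"] = false,
                      _["t_elapsed"] = t_max);
}
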