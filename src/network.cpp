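#include <Rcpp.h>
using namespace Rcpp;

// Sparse recurrent conductance-based LIF network with a per-neuron
// metabolic state MS. MS is a bounded cost-tracking reservoir: it is
// charged per synaptic event and per emitted spike and relaxes back
// toward ms_rest. It drives a saturating membrane current
// I_M = clamp(im_gain * (MS - ms_neutral), -im_bound, +im_bound),
// depolarising when the neuron is under-spent and hyperpolarising when
// it is over-spent. Spike delivery is delayed by one step. Units:
// mV, ms, nS, pF, pA. Randomness (initial conditions, Poisson drive)
// is drawn from R's RNG, so runs are reproducible via set.seed().

// [[Rcpp::export]]
List network_simulate_cpp(int n_exc, int n_inh,
                          IntegerVector adj_ptr, IntegerVector adj_idx,
                          NumericVector par,
                          double duration, double stim_off, double dt,
                          IntegerVector record_ids, int record_every) {
  const int n = n_exc + n_inh;
  const double c_m = par["c_m"], g_leak = par["g_leak"],
               v_rest = par["v_rest"], v_thresh = par["v_thresh"],
               v_reset = par["v_reset"], refractory = par["refractory"],
               e_ex = par["e_ex"], e_in = par["e_in"],
               tau_ex = par["tau_ex"], tau_in = par["tau_in"],
               w_ex = par["w_ex"], w_in = par["w_in"], w_ext = par["w_ext"],
               rate_ext = par["rate_ext"],
               ms_max = par["ms_max"], ms_rest = par["ms_rest"],
               ms_neutral = par["ms_neutral"], tau_ms = par["tau_ms"],
               cost_e = par["cost_e"], cost_i = par["cost_i"],
               cost_spike = par["cost_spike"],
               im_gain = par["im_gain"], im_bound = par["im_bound"];
  const bool ext_costs = par["ext_costs"] != 0.0;

  const int n_steps = (int)std::round(duration / dt);
  const double dec_e = std::exp(-dt / tau_ex);
  const double dec_i = std::exp(-dt / tau_in);
  const double lambda_ext = rate_ext * dt / 1000.0;

  std::vector<double> V(n), ge(n, 0.0), gi(n, 0.0), ms(n), refr(n, 0.0);
  std::vector<double> cum_cost(n, 0.0);
  std::vector<long> cnt_e(n, 0), cnt_i(n, 0), cnt_ext(n, 0), cnt_spk(n, 0);
  for (int i = 0; i < n; ++i) {
    V[i] = v_rest + (v_thresh - v_rest) * unif_rand();
    ms[i] = ms_neutral + (ms_rest - ms_neutral) * unif_rand();
  }

  std::vector<int> spiking, spiking_next;
  spiking.reserve(n); spiking_next.reserve(n);

  std::vector<double> sp_t; std::vector<int> sp_id;
  std::vector<double> sp_ms;

  const int k_rec = record_ids.size();
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix ms_tr(n_rec, k_rec), isyn_tr(n_rec, k_rec),
                im_tr(n_rec, k_rec);
  NumericVector rec_times(n_rec);
  int r = 0;
  std::vector<int> rec_col(n, -1);
  for (int k = 0; k < k_rec; ++k) rec_col[record_ids[k] - 1] = k;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // deliver last step's spikes
    for (size_t si = 0; si < spiking.size(); ++si) {
      const int j = spiking[si];
      const bool exc = j < n_exc;
      for (int e = adj_ptr[j]; e < adj_ptr[j + 1]; ++e) {
        const int k = adj_idx[e];
        if (exc) {
          ge[k] += w_ex; ms[k] -= cost_e; cum_cost[k] += cost_e;
          ++cnt_e[k];
        } else {
          gi[k] += w_in; ms[k] -= cost_i; cum_cost[k] += cost_i;
          ++cnt_i[k];
        }
      }
    }
    spiking.clear();

    // external Poisson drive
    if (t < stim_off && lambda_ext > 0.0) {
      for (int i = 0; i < n; ++i) {
        const int n_ev = (int)R::rpois(lambda_ext);
        if (n_ev > 0) {
          ge[i] += n_ev * w_ext;
          cnt_ext[i] += n_ev;
          if (ext_costs) {
            ms[i] -= n_ev * cost_e;
            cum_cost[i] += n_ev * cost_e;
          }
        }
      }
    }

    const bool record_now = (step % record_every == 0) && r < n_rec;
    if (record_now) rec_times[r] = t;

    for (int i = 0; i < n; ++i) {
      double im = im_gain * (ms[i] - ms_neutral);
      if (im > im_bound) im = im_bound;
      if (im < -im_bound) im = -im_bound;

      double isyn = -ge[i] * (V[i] - e_ex) - gi[i] * (V[i] - e_in);

      if (refr[i] > 0.0) {
        refr[i] -= dt;
        V[i] = v_reset;
      } else {
        V[i] += dt * (-g_leak * (V[i] - v_rest) + isyn + im) / c_m;
        if (!R_finite(V[i]))
          stop("membrane potential of neuron %d became non-finite at "
               "t = %f ms", i + 1, t);
        if (V[i] >= v_thresh) {
          sp_id.push_back(i + 1);
          sp_t.push_back(t + dt);
          sp_ms.push_back(ms[i]);
          spiking_next.push_back(i);
          V[i] = v_reset;
          refr[i] = refractory;
          ms[i] -= cost_spike; cum_cost[i] += cost_spike;
          ++cnt_spk[i];
        }
      }

      ms[i] += dt * (ms_rest - ms[i]) / tau_ms;
      if (ms[i] < 0.0) ms[i] = 0.0;
      if (ms[i] > ms_max) ms[i] = ms_max;

      ge[i] *= dec_e;
      gi[i] *= dec_i;

      if (record_now && rec_col[i] >= 0) {
        const int k = rec_col[i];
        ms_tr(r, k) = ms[i];
        isyn_tr(r, k) = isyn;
        im_tr(r, k) = im;
      }
    }
    if (record_now) ++r;
    std::swap(spiking, spiking_next);
  }

  IntegerMatrix counters(n, 4);
  for (int i = 0; i < n; ++i) {
    counters(i, 0) = (int)cnt_e[i];
    counters(i, 1) = (int)cnt_i[i];
    counters(i, 2) = (int)cnt_ext[i];
    counters(i, 3) = (int)cnt_spk[i];
  }
  colnames(counters) = CharacterVector::create("exc_events", "inh_events",
                                               "ext_events", "spikes");

  return List::create(
    _["spike_id"] = wrap(sp_id),
    _["spike_time"] = wrap(sp_t),
    _["spike_ms"] = wrap(sp_ms),
    _["rec_times"] = rec_times[Range(0, std::max(0, r - 1))],
    _["ms_traces"] = ms_tr(Range(0, std::max(0, r - 1)), _),
    _["isyn_traces"] = isyn_tr(Range(0, std::max(0, r - 1)), _),
    _["im_traces"] = im_tr(Range(0, std::max(0, r - 1)), _),
    _["counters"] = counters,
    _["cum_cost"] = wrap(cum_cost),
    _["final_ms"] = wrap(ms));
}
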