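model: net
params:
  n_exc: 800
  n_inh: 200
  p_connect: 0.02
  c_m: 200.0
  g_leak: 10.0
  v_rest: -60.0
  v_thresh: -50.0
  v_reset: -60.0
  refractory: 5.0
  e_ex: 0.0
  e_in: -80.0
  tau_ex: 5.0
  tau_in: 10.0
  w_ex: 2.0
  w_in: 20.0
  w_ext: 2.0
  rate_ext: 300.0
  ms_max: 1.0
  ms_rest: 0.8
  ms_neutral: 0.5
  tau_ms: 1000.0
  cost_e: 0.0005
  cost_i: 0.0005
  cost_spike: 0.01
  im_gain: 600.0
  im_bound: 150.0
  ext_costs: yes
  dt: 0.1
duration: 1000.0
dt: 0.1
seed: 1
out_dir: '.'
record_every: 10
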