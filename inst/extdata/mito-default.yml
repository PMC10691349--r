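model: mito
params:
  f_ret: 1.0
  f_fet: 1.0
  tau_ros: 200.0
  k_pyr: 0.05
  pyr_max: 1.0
  k_tca: 0.1
  k_etc: 0.2
  n_pump: 2.0
  k_synth: 0.5
  k_ant: 1.0
  k_leak: 0.005
  km_use: 0.05
  ca_coupling: 0.01
  baseline_cost: 0.01
  q: 0.05
  q_kernel_duration: 5.0
  q_kernel_shape: rectangular
duration: 1000.0
dt: 0.1
seed: 1
out_dir: '.'
record_every: 10
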