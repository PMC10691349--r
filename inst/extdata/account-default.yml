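model: account
params:
  theta_ret: 0.15
  theta_fet: -0.15
  refractory: 5.0
  baseline_cost: 0.01
  q: 0.3
  q_kernel_duration: 20.0
  c_bar: 0.05
  c_max: 0.1
  tau_atp: 50.0
  tau_ros: 100.0
  ros_min: 0.1
  v_slope: 20.0
duration: 1000.0
dt: 0.1
seed: 1
out_dir: '.'
record_every: 10
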