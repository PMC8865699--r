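# Classical-conditioning paradigm (scaled network, fast plasticity).
experiment: conditioning
network:
  n_e: 1000
  n_i: 250
  scaled_preset: true
plasticity:
  tau_ca_s: 1
  beta_a: 0.4
  beta_d: 0.4
  nu_target_hz: 8
  delta_t_s_ms: 10
protocol:
  t_growth_s: 100
sim:
  dt_ms: 0.5
seeds:
  construction: 1
  drive: 2
  rewiring: 3
  analysis: 4
output_dir: engramnet_conditioning
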