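# Grow a scaled network (N_E = 1000 with full-scale static in-degrees)
# to its homeostatic equilibrium.
experiment: grow
network:
  n_e: 1000
  n_i: 250
  scaled_preset: true
plasticity:
  tau_ca_s: 10
  beta_a: 2
  beta_d: 2
  nu_target_hz: 8
  delta_t_s_ms: 100
protocol:
  t_growth_s: 500
  record_every_s: 10
sim:
  dt_ms: 0.5
seeds:
  construction: 1
  drive: 2
  rewiring: 3
  analysis: 4
output_dir: engramnet_grow
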