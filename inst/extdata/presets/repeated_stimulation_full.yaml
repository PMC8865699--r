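# Full-scale repeated-stimulation parameter set of the reference
# experiments (N_E = 10000; hours of CPU time — for completeness).
experiment: repeated_stimulation
network:
  n_e: 10000
  n_i: 2500
  scaled_preset: false
plasticity:
  tau_ca_s: 10
  beta_a: 2
  beta_d: 2
  nu_target_hz: 8
  delta_t_s_ms: 100
protocol:
  t_growth_s: 500
  cycles: 8
  stim_s: 150
  relax_s: 150
  mult: 1.05
  ensemble_fraction: 0.1
  record_every_s: 15
sim:
  dt_ms: 0.1
seeds:
  construction: 1
  drive: 2
  rewiring: 3
  analysis: 4
output_dir: engramnet_repeated_full
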