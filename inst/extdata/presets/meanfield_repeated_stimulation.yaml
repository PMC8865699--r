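# Population mean-field surrogate of the repeated-stimulation protocol.
experiment: meanfield_repeated_stimulation
plasticity:
  tau_ca_s: 10
  beta_a: 2
  beta_d: 2
  nu_target_hz: 8
protocol:
  cycles: 8
  stim_s: 150
  relax_s: 150
  mult: 1.05
  eta: 0.7
  record_every_s: 5
seeds:
  construction: 1
  drive: 2
  rewiring: 3
  analysis: 4
output_dir: engramnet_meanfield
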