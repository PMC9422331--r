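# Example pipeline configuration: override any subset of parameters.
cann:
  sigma_noise: 6
  beta_scale: 1.0
generator:
  n_neurons: 115
  seed: 7
decision:
  alpha_bal: 0.9
n_trials: 50
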