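# AM sweep, degradation regulation: branch means 0.1/0.025 on the decay
# rate, output mean calibrated to 15, period T = 200 s.
signal:
  upper_mean: 0.1
  lower_mean: 0.025
  amplitude_var: 0.01
  duration: 3
  regulation: degradation
  modulation: AM
model:
  target_mean: 15
experiment:
  type: mi-sweep
  period: 200
  on_times: [20, 40, 60, 80, 100, 120, 140, 160, 180]
  noise_levels: [0, 0.001, 0.01]
  n_replicates: 1000
  n_batches: 10
  seed: 1
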