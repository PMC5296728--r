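# AM sweep, transcription regulation: MI and EC vs ON-time at fixed period
# T = 200 s, amplitude variances 0/0.001/0.01, noise refresh D = 3 s,
# branch means 0.8/0.1, output mean calibrated to 15.
signal:
  upper_mean: 0.8
  lower_mean: 0.1
  amplitude_var: 0.01
  duration: 3
  regulation: transcription
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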