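# Signal-duration sweep: AM amplitude variance fixed at 0.01, refresh
# intervals D bracketing the mRNA relaxation time, output mean 15.
signal:
  upper_mean: 0.8
  lower_mean: 0.1
  amplitude_var: 0.01
  regulation: transcription
  modulation: AM
model:
  target_mean: 15
experiment:
  type: duration-sweep
  period: 200
  on_times: [20, 40, 60, 80, 100, 120, 140, 160, 180]
  durations: [3, 10, 50]
  n_replicates: 1000
  n_batches: 10
  seed: 1
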