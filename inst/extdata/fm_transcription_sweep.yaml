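# FM sweep, transcription regulation: width CV^2 ("Noise") 0/0.1/1/3,
# levels 0.8/0.1, period T = 200 s, output mean calibrated to 15.
signal:
  upper_mean: 0.8
  lower_mean: 0.1
  regulation: transcription
  modulation: FM
model:
  target_mean: 15
experiment:
  type: mi-sweep
  period: 200
  on_times: [20, 40, 60, 80, 100, 120, 140, 160, 180]
  noise_levels: [0, 0.1, 1, 3]
  n_replicates: 1000
  n_batches: 10
  seed: 1
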