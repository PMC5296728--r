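# Stochastic focusing, FM degradation regulation: decay-rate levels
# 0.1/0.025, constant transcription rate 0.5, ON/OFF ratio 1,
# width noise 0/0.1/1/3.
signal:
  upper_mean: 0.1
  lower_mean: 0.025
  regulation: degradation
  modulation: FM
model:
  target_mean: null
  fixed_rate: 0.5
experiment:
  type: sf-curve
  periods: [25, 50, 100, 200, 400]
  noise_levels: [0, 0.1, 1, 3]
  on_off_ratio: 1
  n_signals: 200
  seed: 1
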