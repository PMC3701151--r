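# AMPA binding-rate sweep inside the oscillatory regime
preset: defaults
set: {ampa.beta: 1}
noise: {mean: -67.5, sd: 2, dt_hold: 1, seed: 42}
solver: {duration: 600000, report_dt: 1}
sweep:
  parameter: ampa.alpha
  grid: [2, 5, 10, 20, 30]
  n_trials: 20
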