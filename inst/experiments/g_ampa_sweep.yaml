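# joint AMPA conductance sweep from the fast-kinetics configuration
preset: defaults
set: {ampa.alpha: 20, ampa.beta: 1}
noise: {mean: -67.5, sd: 2, dt_hold: 1, seed: 42}
solver: {duration: 600000, report_dt: 1}
sweep:
  parameter: g_ampa
  grid: [0.1, 0.15, 0.2, 0.25, 0.3]
  n_trials: 20
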