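# TRN->TCR GABA_A conductance sweep from the spindling preset
preset: spindling
noise: {mean: -67.5, sd: 2, dt_hold: 1, seed: 42}
solver: {duration: 600000, report_dt: 1}
sweep:
  parameter: gabaa_n2t.g_max
  grid: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7]
  n_trials: 20
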