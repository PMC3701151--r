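# joint GABA_A + GABA_B blockade on the TRN->TCR pathway
preset: defaults
set: {gabaa_n2t.g_max: 0, gabab_n2t.g_max: 0}
noise: {mean: -67.5, sd: 2, dt_hold: 1, seed: 42}
solver: {duration: 600000, report_dt: 1}
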