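# Nullclines of the reduced model under moderate GABA: geometry of the
# SNIC bottleneck.
kind: nullclines
label: nullclines-gaba
seed: 1
syn: {g_gaba: 0.15}
nullclines:
  v_range: [-90, -25]
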