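# AMPA-induced depolarization block in the full model.
kind: sweep
label: ampa-block
seed: 1
duration: 8000
transient: 2000
sweep:
  x: {param: g_ampa, from: 0, to: 3, n: 16}
  y: {param: g_gaba, from: 0, to: 0, n: 1}
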