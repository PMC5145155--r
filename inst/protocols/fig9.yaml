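# Tonic AMPA x GABA plane: firing persists in a much smaller GABA range
# than under NMDA; GABA cannot rescue AMPA-induced depolarization block.
kind: sweep
label: ampa-gaba-plane
seed: 1
duration: 8000
transient: 2000
sweep:
  x: {param: g_ampa, from: 0, to: 3, n: 16}
  y: {param: g_gaba, from: 0, to: 4, n: 16}
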