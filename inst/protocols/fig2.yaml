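# Tonic NMDA x GABA conductance plane: firing-rate map, balance band and
# the reference balanced cell (g_nmda = 16.9, g_gaba = 5 mS/cm^2).
kind: sweep
label: nmda-gaba-plane
seed: 1
duration: 10000
transient: 2000
sweep:
  x: {param: g_nmda, from: 0, to: 30, n: 20}
  y: {param: g_gaba, from: 0, to: 8, n: 20}
  balance_band: [5.5, 16.6]
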