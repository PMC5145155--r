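# Asynchronous Glu (35 Poisson trains, ~10 Hz, NMDA coincidence-gated) and
# GABA-population drive: rate and regularity of the DA neuron in vivo-like
# background state.
kind: async
label: asynchronous-background
seed: 1
duration: 20000
async:
  g_nmda: 10
  g_gaba: 4
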