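# Pure Ca2+/SK oscillatory mechanism (subthreshold Na+ blocked): GABA sweep
# terminates oscillations through the Hopf branch (type II).
kind: classify
label: ca-k-mechanism-gaba-sweep
seed: 1
variant: {include_spike_currents: false, include_sna: false}
classify:
  param: g_gaba
  values: [0.02, 0.1, 0.2, 0.3, 0.4, 0.5]
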