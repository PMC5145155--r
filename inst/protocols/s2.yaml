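# Full model (with spike-producing currents) GABA sweep: same transition
# class as the reduced model.
kind: classify
label: full-model-gaba-sweep
seed: 1
dt: 0.025
classify:
  param: g_gaba
  values: [0.05, 0.15, 0.25, 0.35, 0.5]
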