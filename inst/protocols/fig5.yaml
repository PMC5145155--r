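# Frequency growth under NMDA with spike-producing currents removed: the
# reduced model tracks the full model's rates.
kind: fi
label: nmda-fi-reduced
seed: 1
variant: {include_spike_currents: false}
duration: 8000
transient: 2000
dt: 0.05
fi:
  param: g_nmda
  from: 0
  to: 3
  n: 13
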