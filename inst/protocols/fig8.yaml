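# Combined ohmic synapse: Bogdanov-Takens boundary between type I (SNIC)
# and type II (Hopf) transitions in the reversal potential.
kind: bt
label: bt-boundary
seed: 1
variant: {include_spike_currents: false}
bt:
  e_range: [-90, -60]
  g_max: 6
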