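# BT boundary as a function of NMDA co-activation: the type I/II boundary
# shifts to lower combined reversal potentials.
kind: bt
label: bt-boundary-nmda
seed: 1
variant: {include_spike_currents: false}
syn: {g_nmda: 0.5}
bt:
  e_range: [-90, -60]
  g_max: 8
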