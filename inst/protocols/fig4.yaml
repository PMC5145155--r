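# Voltage and total-current time series of the balanced state (bottleneck
# effect during the interspike interval).
kind: trace
label: balanced-state-trace
seed: 1
duration: 12000
transient: 2000
syn: {g_nmda: 16.9, g_gaba: 5}
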