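# Background firing of the shipped parameter set (no synaptic input,
# no applied current): the 1-5 Hz tonic pacemaker.
kind: trace
label: background-pacemaking
seed: 1
duration: 12000
transient: 2000
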