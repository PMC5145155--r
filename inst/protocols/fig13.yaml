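# EtOH condition: Ih, AMPA and GABA currents scaled up under 1-Hz
# sine-modulated correlated NMDA drive; synchrony and dopamine release.
kind: etoh
label: etoh
seed: 1
duration: 14000
population:
  n_neurons: 50
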