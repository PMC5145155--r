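# Heterogeneous DA population under correlated OU NMDA drive: control vs
# tonic AMPA/GABA background tone; synchrony and dopamine release.
kind: population
label: population-tonic-tone
seed: 1
duration: 14000
population:
  n_neurons: 50
  mu: 1.5
  sigma: 0.5
  c: 0.5
  tau: 5
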