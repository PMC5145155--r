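# Ih and the equilibrium-branch folds: critical gh where the saddle-node
# pair of the branch vanishes (transition to the pure LC-fold scenario).
kind: cusp
label: ih-cusp
seed: 1
variant: {include_spike_currents: false}
cusp:
  gh_range: [0, 20]
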