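# F-I curve under hyperpolarizing applied current (full model): smooth
# transition to zero frequency.
kind: fi
label: hyperpolarizing-fi
seed: 1
duration: 10000
transient: 2000
fi:
  param: i_app
  from: -6
  to: 0
  n: 13
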