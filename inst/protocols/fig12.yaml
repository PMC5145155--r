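# Reward-value coding by type I and type II configurations (two-pulse
# NMDA protocol).
kind: reward
label: reward-coding
seed: 1
reward:
  values: [0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
  type: I
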