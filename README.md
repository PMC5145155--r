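# daneuron

Conductance-based modelling of midbrain dopamine (DA) neuron excitability:
a single-compartment Hodgkin–Huxley-type model of the DA neuron, the
synthetic synaptic inputs that drive it, and the dynamical-systems analysis
that classifies its excitability as type I or type II — plus heterogeneous
population simulations with synaptic dopamine release.

## The science

Midbrain DA neurons fire tonically at 1–5 Hz.  In this model the pacemaker
is a subthreshold Ca²⁺/SK oscillator — an L-type Ca²⁺ current `I_Ca`
interacting with an SK-type Ca²⁺-activated K⁺ current `I_KCa` — augmented
by a voltage-gated K⁺ current, a subthreshold (persistent) Na⁺ current,
the hyperpolarization-activated cation current `I_h`, a depolarized leak,
and fast spike-producing currents (`I_Na`, `I_DR`):

    c_m dv/dt = g_Ca(v)(E_Ca − v) + (g_KCa([Ca]) + g_K(v) + ḡ_DR n⁴)(E_K − v)
              + (g_sNa(v) + ḡ_Na m³h)(E_Na − v) + g_l(E_l − v)
              + g_h q (E_h − v) + I_NMDA + I_AMPA + I_GABA + I_app

    d[Ca]/dt  = (2β/(r z F)) (g_Ca(v) + 0.1 g_l)(E_Ca − v) − (2β P_Ca/r) [Ca]

with `g_KCa = ḡ_KCa [Ca]⁴/([Ca]⁴ + K_SK⁴)` and an NMDA conductance carrying
the Mg²⁺ block `ḡ_NMDA / (1 + 0.1[Mg] e^(−0.062 v))`.  Removing the
spike-producing currents leaves a two-dimensional `(v, [Ca])` system
amenable to nullcline and bifurcation analysis.

The questions the package answers, for whoever needs a tested
implementation of this class of analysis:

* where on the NMDA×GABA conductance plane excitation and inhibition
  balance into background-like low-frequency firing, and why excessive
  NMDA (but not its GABA-compensated combination) produces depolarization
  block;
* whether the transition from spiking to rest is a SNIC (type I
  excitability: arbitrarily slow firing at onset) or an Andronov–Hopf /
  limit-cycle fold (type II: a discontinuous frequency jump), and how the
  subthreshold Na⁺ current, `I_h`, AMPA co-activation and the GABA
  reversal potential switch between the two — including the
  Bogdanov–Takens point separating the regimes in the reversal potential
  of the combined ohmic synapse;
* how excitability type shapes population function: synchrony and
  Michaelis–Menten dopamine release (`d[DA]/dt = DA_max δ(t − t_spike) −
  V_max [DA]/(K_m + [DA])`) under correlated Ornstein–Uhlenbeck NMDA
  drive, in control, tonic-synaptic-tone, ethanol and reward-coding
  protocols.

All inputs are generated internally: Poisson glutamate trains gated by
spike coincidence onto NMDA receptors, a simulated population of 30
Wang–Buzsáki GABA interneurons, tonic conductances, and correlated OU
conductance traces.

## Worked example

```r
library(daneuron)
p <- da_params()                      # shipped, calibrated parameter set

# background pacemaking (no input)
sim <- integrate_da(p, duration = 12000, transient = 2000)
firing_stats(sim$spikes, transient = 2000)$rate
#> [1] 2.653497                        # tonic firing in the 1-5 Hz band

# classify the spiking-to-rest transition under growing GABA conductance
bp <- classify_transition(p, reduced_variant(), "g_gaba",
                          grid = seq(0.05, 0.5, length.out = 6))
bp$type
#> [1] "SNIC"                          # type I: the fold of equilibria
                                      # lands on the cycle

# ... and the same sweep without the subthreshold Na+ current
bp2 <- classify_transition(p, reduced_variant(include_sna = FALSE),
                           "g_gaba", grid = seq(0.02, 0.5, length.out = 6))
bp2$type
#> [1] "LCFold"                        # type II: the cycle dies at finite
                                      # amplitude on the Hopf branch

# Bogdanov-Takens boundary of the combined ohmic synapse
bt <- bt_boundary(p, reduced_variant(), e_range = c(-90, -60), g_max = 6)
bt$e_bt
#> [1] -72.28271                       # mV; type I below, type II above
```

`run_protocol()` executes the shipped YAML protocols
(`system.file("protocols", package = "daneuron")`: `fig1.yaml` …
`fig13.yaml`, `s1.yaml` … `s3.yaml`, `calibration.yaml`) and writes tidy
CSV tables plus a JSON manifest:

```r
run_protocol(system.file("protocols", "calibration.yaml",
                         package = "daneuron"),
             out_dir = "out/calibration")
```

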