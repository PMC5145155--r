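---
title: "Excitability of a model dopamine neuron: model, calibration and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitability of a model dopamine neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(daneuron)
```

This vignette is the package's own account of its science: the model and
its assumptions, the constants that had to be calibrated, the numerical
and design choices behind the analysis machinery, what the synthetic
inputs do and do not emulate, and the known limitations of the shipped
calibration.

## The model

The DA neuron is a single compartment.  Its voltage equation carries
eight intrinsic currents — an instantaneously gated L-type Ca²⁺ current,
an SK-type Ca²⁺-activated K⁺ current (Hill coefficient 4 in Ca²⁺), a
Boltzmann-gated K⁺ current, a delayed rectifier (`n⁴`), an instantaneous
subthreshold (persistent) Na⁺ current, a fast spike Na⁺ current
(`m∞³ h`), a depolarized leak (`E_l = −35` mV, standing in for the
nonselective cation currents that depolarize DA cells between spikes),
and the hyperpolarization-activated cation current `I_h` (activation
midpoint −95 mV) — plus NMDA, AMPA and GABA receptor currents.  Only the
NMDA conductance is voltage dependent, through the Mg²⁺ block
`1/(1 + 0.1·[Mg]·e^{−0.062 v})` with `[Mg] = 0.5`, implemented exactly as
published (the printed magnesium level is far below the physiological
millimolar range; we keep it because the resulting voltage dependence is
what the rest of the calibration is built on).

Ca²⁺ enters through the L-type channel and through a Ca²⁺ component of
the leak (10% of `g_l`); entry through NMDA receptors is omitted
(spatial segregation of NMDA receptors and SK channels).  The balance
equation converts current density to concentration through
`2β/(r z F)` and removes Ca²⁺ with a first-order pump.  Units are mV,
ms, mS/cm², µF/cm², µM throughout; the two derived conversion constants
(`ca_gain`, `ca_pump`) are computed once in `da_params()` so that Ca²⁺
stays in µM.

Two model variants matter.  The *full* model carries the spike-producing
currents and registers a spike at 0 mV.  The *reduced* model removes
them — the remaining `(v, [Ca])` system (plus `q` when `I_h` is active)
is what nullcline and bifurcation analysis applies to — and registers a
spike when the subthreshold oscillation crosses −40 mV, the empirical
spike-trigger voltage of DA cells.  The pure Ca²⁺/SK variant
additionally blocks the subthreshold Na⁺ current (and the Ca²⁺ leak
term, which belongs to the same calibration layer) to isolate the core
oscillatory mechanism.

## What had to be calibrated, and how

The published parameter table fixes the maximal conductances and
reversal potentials but not: the L-type activation curve (its rate
functions are defined in an antecedent model we do not have), the Ca²⁺
handling constants (`β`, `r`, `z`, `F`, `P_Ca`), the SK half-activation
`K_SK`, the `I_h` reversal, the interneuron leak conductance, or the
interneuron drive.  We adopted the standard values `β = 0.05`, `r = 20`
µm, `z = 2`, `F = 96485` C/mol from the Ca²⁺–K⁺ model lineage, gave the
L-type activation a sigmoid steady state, and calibrated the remaining
constants against the model's reference behaviours: 1–5 Hz background
firing, the balanced state under tonic NMDA/GABA co-activation, the
≤ 10 Hz AMPA-driven ceiling, the −72.26 mV boundary between excitability
types, the ~7 mS/cm² `I_h` cusp, and the bifurcation structure (SNIC
with the subthreshold Na⁺ current, Hopf branch without it).

Two structural facts shaped the outcome.  First, the model has an exact
scaling symmetry: rescaling Ca²⁺ by `a` while rescaling `K_SK` by `1/a`
(at fixed `β·P_Ca`) leaves every observable unchanged, so the static
geometry depends only on the L-type midpoint and slope and on the
product `K_SK·P_Ca`, while `β` sets the Ca²⁺ time scale alone.  Second,
those three static degrees of freedom are not enough to satisfy every
anchor simultaneously: the boundary reversal potential, the `I_h` cusp
position, the no-sNa Hopf structure and the 1.5 Hz balanced state pull
the fold of the equilibrium branch in incompatible directions.  The
shipped defaults (`vhalf_ca = −41.4` mV, `k_ca = 3` mV, `K_SK = 1.5`
µM, `P_Ca = 6.5e−5`, `E_h = −20` mV) prioritize the excitability-type
structure, the type I/II boundary and the AMPA ceiling; the residual
deviations are listed under *Limitations*.  The published "activation
threshold ~ −50 mV" of the L-type current is honored as the *foot* of
the calibrated sigmoid (about 6% activation at −50 mV), not its
midpoint.

The interneuron (Wang–Buzsáki fast-spiking model, `n⁴` K⁺ current,
leak 0.1 mS/cm²) receives per-neuron applied currents drawn uniformly
from a small interval calibrated so intrinsic rates fall inside the
12–22 Hz band; initial voltages are drawn hyperpolarized of the
neuron's coexisting depolarized rest state so every cell starts on the
firing attractor.

## Synthetic inputs

`poisson_glu_trains()` generates the asynchronous glutamate drive (35
independent Poisson trains at ~10 Hz); `coincidence_drive()` converts
the pooled train into the binary NMDA input, which is active for 1 ms
whenever two or more spikes arrive within a 1 ms window (both the
window and the threshold are configuration values; the published account
gives only "two or more spikes").  Receptor gates integrate the
activation/deactivation kinetics exactly branch by branch, so they can
never leave [0, 1].  `gaba_population_drive()` integrates the 30
interneurons and returns the population-mean GABA gate, which is
quasi-constant (coefficient of variation ≈ 0.2) for an asynchronous
population and strongly pulsatile for a single cell.  Tonic receptor
activation (`s = 1`) approximates this asynchronous drive well: at
matched *effective* conductance (maximal conductance × mean gate) the
tonic and asynchronous firing rates agree within a few percent.  The
comparison must be made at matched effective conductance because the
asynchronous gates average well below 1 (~0.67 for NMDA, ~0.2 for
GABA).

Correlated NMDA fluctuations are sums of Ornstein–Uhlenbeck processes
with correlation time 5 ms, built with the exact discretization (not
Euler), so their stationary mean, variance and autocorrelation are
correct at any step.  The published linear weighting of common and
independent components does not preserve variance; we use the
variance-preserving `√(1−c)`, `√c` weighting so the stated σ *is* the
conductance standard deviation and `c` the pairwise trace correlation.
Negative excursions are clipped at zero before use as conductances.
The sine-modulated variant multiplies the mean by `1 + depth·sin(2πft)`.

What the generator does *not* emulate: synaptic depression or
facilitation, dendritic filtering, conductance-dependent noise
statistics, or any non-Poisson structure in the afferent trains.
Passing tests therefore certify the pipeline under idealized drive, not
under real in vivo input statistics.

## Simulation engine

The production integrator is a fixed-step RK4 kernel in C++ (step 0.025
ms for the full model — resolving the fast Na⁺ spike — and 0.05 ms for
the reduced one); `deSolve::lsoda` on the same R-side vector field is
the independent cross-check in the tests, never the production path.
Spikes are threshold upcrossings with a 2 ms refractory guard against
double counts on dense grids.  Rates are inverse mean interspike
intervals; the ISI coefficient of variation uses 200 ISIs (the most
recent 200) and is undefined below 201 spikes.  Sweeps discard a 2 s
transient and use 10 s per point by default; the heavier acceptance
computations use the same settings, and the test suite scales problem
sizes (shorter per-point durations, 20×20 grids, 50-neuron populations)
chosen to keep each analysis well-resolved at desk scale.
Depolarization block is declared when a post-transient segment has no
spikes, mean voltage above −45 mV (−50 mV for the reduced model) and
peak-to-peak amplitude below 5 mV — the published account gives no
numeric criterion, so the cutoffs are configuration values.

## Bifurcation analysis

All gating steady states are single-valued in voltage, so every
equilibrium lies on a branch parameterized by `v`; `find_equilibria()`
enumerates them by a grid scan with root polishing and certifies each
root by its residual (< 1e−8) and a finite-difference Jacobian.  This
simulation-plus-algebra route (rather than a continuation library)
keeps every certificate explicit and testable.

`classify_transition()` bisects the last spiking parameter value and
issues the verdict from two ingredients: the *first-stable-equilibrium
event* along the sweep (does stability arrive through a fold of the
branch — the SNIC route — or through an eigenvalue crossing of a
persistent equilibrium — the Hopf route), and the onset frequency and
cycle amplitude measured by simulation near the transition.  A
subcritical Hopf whose cycle dies at finite amplitude at the nearby
fold of cycles is reported as `LCFold`; it belongs to the type II
(Hopf-branch) outcome.  Homoclinic events on the unstable cycle branch
are not certified — they do not affect the observable verdicts.

The onset-frequency threshold ε separating "arbitrarily slow" from a
discontinuous jump is 0.7 Hz.  The value is derived from the model
itself: long warm-started probes show the SNIC-side transitions
terminate at a minimum sustained rate of ~0.5 Hz (the stable cycle is
destroyed by a nearby fold of cycles just before the equilibrium fold),
while the smallest Hopf-branch jump is ~0.9 Hz, so 0.7 separates the
classes with margin on both sides.

`bt_boundary()` bisects the reversal potential of the combined ohmic
synapse on the flip of the fold-versus-crossing verdict; at the
boundary the transition equilibrium's Jacobian has a near-double-zero
eigenvalue pair, which the result reports as a cross-check.
`critical_gh_fold()` works on the closed-form equilibrium branch
`I_app(v)` and bisects the `g_h` at which its hyperpolarizing-side
slope stops changing sign; the restriction to the branch portion at
`I_app ≤ 0` is deliberate — the depolarized knee of the branch (the
upper fold associated with depolarization block) is not the saddle-node
pair that interrupts the limit cycle.

With `I_h` included the reduced system is three-dimensional
(`v, [Ca], q`); nullclines are drawn on the `(v, [Ca])` plane with `q`
at its voltage steady state, and are labeled as such.

## Population protocols

Heterogeneity is a per-neuron leak drawn uniformly within ±15% of the
reference (a range that keeps every neuron tonically active in
control).  The population size defaults to 50.  The synchrony index is
the variance of the binned population rate normalized by its
expectation under independent firing, estimated by circular shifts of
each train (which preserve all single-neuron statistics); independent
Poisson rasters calibrate to 1.  Dopamine release applies the
per-spike increment to the pooled population spike train, as an
instantaneous state increment (not a narrow pulse), with
Michaelis–Menten uptake; at that pooled drive the transporter runs
near saturation, so the net rise of the concentration across the
stimulus window is the release measure the protocols compare.

The tonic-tone protocol requires its AMPA/GABA background to keep the
mean rate within 10% of control (it errs otherwise); the shipped tone
(`g_AMPA = 0.4`, `g_GABA = 1.0` mS/cm²) satisfies this and leaves the
population measurably more synchronizable by the shared NMDA
fluctuations.  The EtOH protocol scales a milder standing background
(`0.2/0.5` plus the base `I_h`) by its multipliers (`I_h` ×3.5, AMPA
×3, GABA ×2.5, all ≥ 1; unit multipliers reproduce the control arm bit
for bit) under 1 Hz sine-modulated drive.  The reward protocol maps
reward value to the strength of a second NMDA pulse after a fixed
salience pulse; the type II configuration (tonic AMPA with
compensating GABA) loses the low-value range, the type I configuration
responds gradedly from its background rate.

## Limitations of the shipped calibration

The unprinted L-type rate functions force a reconstruction, and a
single-sigmoid activation cannot satisfy every published anchor at
once.  The shipped defaults reproduce: the 1–5 Hz background band
(2.65 Hz), the type I/II structure and all its switches (subthreshold
Na⁺, `I_h`, AMPA co-activation, GABA reversal), the type I/II boundary
at −72.3 mV, the ≤ 10 Hz AMPA ceiling with block and its rescue
asymmetry, and the population-level synchrony/dopamine contrasts.
They do *not* reproduce: the 1.5 Hz balanced state at
`(g_NMDA, g_GABA) = (16.9, 5)` — the model fires there at ~11 Hz, and
its balance band consequently fits a shallower slope than the
published 3.4; the `I_h` cusp position (~15 mS/cm² rather than ~7);
and the asymptotic square-root frequency scaling of a clean SNIC (the
residual fold of cycles leaves a ~0.5 Hz minimum sustained rate, and
joint log–log fits give an exponent near 0.25).  These deviations are
reported as measured wherever they are measured; no tolerance was
widened to mask them.
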