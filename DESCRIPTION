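Package: daneuron
Title: Conductance-Based Dopamine Neuron Model, Excitability Typing, and
    Population Dopamine Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment conductance-based model of a midbrain dopamine
    (DA) neuron built around a subthreshold Ca2+/SK oscillatory pacemaking
    mechanism augmented by a subthreshold Na+ current, Ih, and fast
    spike-producing currents.  The package generates the synaptic inputs the
    analyses consume (Poisson glutamate trains, a simulated Wang-Buzsaki GABA
    interneuron population, correlated Ornstein-Uhlenbeck NMDA conductances),
    integrates any model variant under any input protocol, computes firing
    statistics, F-I curves, and conductance-plane maps, performs nullcline,
    equilibrium and bifurcation analysis to classify excitability as type I
    (SNIC) or type II (Andronov-Hopf / limit-cycle fold) including the
    Bogdanov-Takens boundary between the two, and simulates heterogeneous DA
    neuron populations with Michaelis-Menten dopamine release under control,
    tonic synaptic tone, ethanol, and reward-coding protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
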