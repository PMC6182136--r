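Package: transokin
Title: Stochastic Kinetics of Transpososome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the assembly kinetics of cut-and-paste transposon
    synaptic complexes (transpososomes) under the two canonical pathways:
    synapsis by naked-end capture (S-NEC), used by transposases that
    multimerize before DNA binding, and synapsis by protein dimerization
    (S-PD), used by monomeric bacterial transposases. Provides mass-action
    reaction-network builders with nonspecific-DNA sequestration and mutant
    handling (active-site DDE to ADE, dimer-interface G462D, single-chain
    dimers), an exact Gillespie direct-method engine, a finite-state
    continuous-time Markov chain oracle (uniformization), mean-field ODE
    integration, dose-response and genome-size sweeps with over-production
    inhibition (OPI) detection, generation-based genomic-invasion
    simulations, archetype parameter ensembles, exponential dwell-time
    generation and recovery, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
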