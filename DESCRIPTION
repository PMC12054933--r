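Package: qifstdp
Title: Spiking QIF Networks with Hebbian and Anti-Hebbian Inhibitory STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of networks of quadratic integrate-and-fire (QIF)
    neurons whose synapses evolve under three spike-timing-dependent
    plasticity (STDP) rules: asymmetric Hebbian for excitatory synapses and
    symmetric Hebbian or anti-Hebbian for inhibitory ones. Provides the
    training, consolidation, damage-recovery, memory-capacity and
    overlapping-stimulus protocols under which such networks form and
    maintain modular memory assemblies, together with the dynamical
    indicators used to characterise them: instantaneous firing rates,
    interspike-interval statistics, spike-phase Kuramoto order parameters,
    weight-change rates, spontaneous-recall detection and stability
    classification. The integration loop is implemented in C++ for speed;
    all plasticity rules are also exposed as pure R functions.
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
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
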