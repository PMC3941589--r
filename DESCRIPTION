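Package: sparsehebb
Title: Sparseness-Driven Differential-Hebbian Synaptic Plasticity Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates long-term synaptic plasticity as stochastic gradient ascent
    on the skewness (or kurtosis) of the postsynaptic membrane potential. The
    resulting differential-Hebbian rule, driven by the product of the synaptic
    current and the time derivative of the local membrane potential, is coupled
    to a reduced ball-and-stick compartmental neuron with AMPA/NMDA synapses,
    voltage-dependent magnesium block, spine compartments, backpropagating
    action potentials and ideal somatic voltage clamp. Protocol runners
    reproduce spike-timing-dependent plasticity (pairing, repetition-frequency
    and location dependence), BCM-type rate-dependent plasticity with priming
    metaplasticity, voltage-clamp induction, and the emergence of lognormal,
    positively skewed synaptic weight distributions in synapse populations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
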