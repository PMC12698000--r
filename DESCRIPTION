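Package: bapboost
Title: Transient bAP-Boosted Synaptic Plasticity in Two-Compartment Spiking Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for self-supervised temporal-pattern learning in
    two-compartment (somatic/dendritic) integrate-and-fire neurons. Implements a
    multiplicative Hebbian plasticity rule driven by a postsynaptic excitability
    signal in three flavors (spike-trace, calcium, and calcium/NMDAR), a
    spike-triggered transient boost of the somato-dendritic coupling conductance
    that emulates backpropagating action potentials, homeostatic synaptic
    rescaling, Poisson input streams with frozen repeated pattern templates,
    experiment protocols (tuning trials, bAP-strength sweeps, jitter robustness,
    initial-bias studies, burst-fraction convergence, STDP pairing protocols),
    and a recurrent network with pre-configured excitatory cell assemblies for
    few-shot pattern learning. Metrics include a selectivity index with a
    persistence-based tuning criterion, signal-to-noise ratios of output spike
    trains, binned spike-train cross-correlations, and weight-distribution
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
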