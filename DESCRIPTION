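Package: striatnet
Title: Striatal Network Connectivity Under Simulated Parkinsonian
    Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how stage-wise morphological changes of
    striatal neurons reshape microcircuit connectivity. Provides SWC
    morphology input/output and morphometry, stepwise dendritic
    truncation and axonal terminal growth transforms, a seeded generator
    of synthetic projection-neuron and fast-spiking interneuron arbors
    calibrated to published morphometrics, touch-detection network
    construction with configurable pruning rules, directed-clique
    (directed flag complex) counting with composition and synapse-weight
    breakdowns, correlated Poisson input generation with synaptic
    strengthening and rewiring compensation on a surrogate
    integrate-and-fire neuron, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
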