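Package: energyScape
Title: Energy Landscape and State-Transition Network Analysis of Binary
    Multivariate Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multivariate time series by exact gradient ascent over the enumerated
    state space, derives the energy landscape of the fitted system (local
    minima, minimax energy barriers, disconnectivity trees), constructs
    directed state-transition networks among stable states, and analyzes
    their organization (hub states, path lengths, UPGMA grouping of
    attractors, coupling-scale perturbation sweeps). Includes a synthetic
    generator of ground-truth models and exact or Gibbs-sampled binary
    time series so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
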