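Package: axonmt
Title: Axonal Microtubule Orientation: Growth-Regime Modelling, Comet-Track
    Analytics and Bundle Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how axonal microtubule (MT) arrays become
    uniformly plus-end-out oriented. Implements a two-state master-equation
    model of MT dynamic instability that separates bounded from unbounded
    growth (with an event-driven stochastic simulator as verification
    oracle), analytics for EB1 comet tracks and tubulin shrinkage events
    extracted from kymographs (filtering, tip-referenced binning,
    catastrophe-rate and growth-length estimation, bootstrapped median
    confidence intervals), fitting of exponential fluorescence gradients of
    tip-enriched anti-catastrophe factors such as p150 and of the power-law
    coupling between local factor concentration and growth length per cycle,
    an agent-based simulator of a dynein cross-linked MT bundle with six MT
    addition models, and generators of synthetic datasets with known ground
    truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
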