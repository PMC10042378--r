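Package: fallrisk
Title: Fall-Risk Metrics and Mean First Passage Times for Metastable Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the fall risk of metastable walking systems. Builds
    absorbing Markov chains from deterministic step-to-step transition
    meshes, computes mean first passage times (steps to fall) from the
    second-largest eigenvalue and from the fundamental matrix, and
    calculates 49 mechanics-based gait metrics (extrapolated centre of
    mass, foot rotation index, short- and long-term Lyapunov exponents,
    joint variability, spatiotemporal statistics) both from brute-force
    step sequences and directly from the chain via visit-weighted
    statistics. Includes a synthetic metastable walker for generating
    study data, convergence analysis of metric accuracy versus number of
    steps, and individual and combined (PCA plus consensus stepwise)
    quadratic models that predict the log mean first passage time.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
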