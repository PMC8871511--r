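Package: csorg
Title: Constrained Self-Organization of Heterarchical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workbench for self-organization under
    informational constraints. Evolves networks of elementary two-tanh map
    units and leaky-tanh reservoir computers with a genetic algorithm,
    quantifies emergent heterarchical structure (feedforward plus feedback
    organization) via layer assignment, edge classification and ablation
    experiments with time-dependent mutual information, and provides a
    constructive Kolmogorov-Arnold-Sprecher superposition module together
    with polynomial-landscape tooling for attractor-based models of
    functional differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
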