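Package: bcv
Title: Bayesian Context-Sensitive Valuation and Choice Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for a Bayesian model of context-sensitive value in
    decision making. Options offer reward amounts on one or more attributes;
    an agent performs sequential conjugate-Gaussian belief updating over each
    attribute's reward population, and the incentive value of each reward is
    the precision-weighted prediction error computed during that update.
    Option values feed a softmax choice rule. The package provides exact
    (order-enumerating) and seeded Monte-Carlo choice-probability engines,
    experiment drivers for within-choice context effects (third-option
    U-shape, similarity/attraction decoy grids, compromise designs), a
    single-level and hierarchical contextual-observation model for
    between-choice effects, and a command-line interface with CSV/JSON
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
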