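Package: TemporalInference
Title: Temporal Bayesian Networks and Belief Updating for Discrete
    Active Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the temporal structure of discrete
    active-inference (hidden Markov) models. Constructs temporal
    directed acyclic graphs in three orders (sequential,
    interpenetrated, and an integrated continuity combining objective
    time with subjective temporality), extracts and verifies Markov
    blankets of the present moment by exhaustive d-separation, and
    implements the softmax belief-propagation equations (message
    potentials, stationary fixed points, and free-energy gradient
    sweeps) together with an exact forward-backward smoothing oracle.
    Includes seeded demonstration experiments for melody surprise
    (protentional fulfilment versus violation) and serial dependence
    in perception, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'temporal-graph.R'
    'generative-model.R'
    'belief-updating.R'
    'exact-oracle.R'
    'demos.R'
    'io.R'
    'cli.R'
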