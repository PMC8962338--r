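Package: ptml
Title: Perturbation-Theory Machine Learning for Multi-Target Inhibitor Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-target QSAR classification that couples property-weighted
    graph descriptors with condition-deviation (Box-Jenkins) features and
    multilayer-perceptron or linear-discriminant classifiers. Computes spectral
    moments of the bond adjacency matrix, Kier-Hall simple and valence
    connectivity indices, edge (bond) connectivity indices, and atom-based
    local stochastic quadratic indices over typed atom groups; curates and
    labels multi-condition bioactivity tables; fits and applies the two-step
    moving-average deviation transform per experimental-condition element;
    trains and evaluates classifiers with global and per-condition metrics and
    a descriptor-range applicability domain; and supports descriptor-propensity
    interpretation, multi-condition screening of candidate molecules, and
    drug-likeness filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    MASS,
    nnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
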