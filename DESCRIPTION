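Package: coneforest
Title: Poincare-Ball Embedding of Graphs with Mixed Hierarchical and
    Non-Hierarchical Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised hyperbolic representation learning for
    heterogeneous graphs that mix multi-root poly-hierarchical taxonomies
    with non-hierarchical link structure. Nodes are embedded in the open
    Poincare ball and trained by projected Riemannian stochastic gradient
    descent on a negative-sampling distance objective, augmented with three
    structural regularizers: a root penalty keeping every tree root within
    hyperbolic distance delta of the origin, a radial ordering penalty
    keeping each parent closer to the origin than its children, and
    hyperbolic entailment-cone penalties placing children (and
    non-hierarchically linked nodes) inside the angular cone their parent
    (or linked hierarchy node) defines. Includes a deterministic synthetic
    forest generator, constraint-satisfaction and reconstruction metrics, a
    frozen-embedding softmax classifier evaluation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    nnet,
    pROC,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
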