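Package: regcn
Title: Community Detection by Structure-Center Refinement and Graph
    Convolutional Self-Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised detection of communities (network modules) in
    undirected, optionally attributed graphs. Initial structure centers are
    selected by a density-peaks criterion (local density times relative
    distance), iteratively refined by alternating graph-convolutional
    partitioning with a simple-path-based local importance update, expanded
    into a pseudo-labeled training set by community-affiliation affinity,
    and used to train a final two-layer graph convolutional classifier that
    partitions the network. Includes planted-partition (stochastic block
    model) generators with block-correlated binary attributes for
    validation, and clustering agreement metrics (best-mapping accuracy,
    normalized mutual information, adjusted Rand index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'regcn-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'graph-io.R'
    'gcn.R'
    'expand.R'
    'metrics.R'
    'synthetic.R'
    'seeding.R'
    'refine.R'
    'pipeline.R'
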