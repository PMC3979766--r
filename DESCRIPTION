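Package: smartclust
Title: Splitting-While-Merging Clustering with Automatic Model-Order Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Splitting-while-merging (SWM) clustering for gene-expression
    and general numeric data, estimating the number of clusters automatically
    with no dataset-dependent parameters. Two engines are provided: a
    competitive-learning algorithm built on the one-prototype-take-one-cluster
    (OPTOC) paradigm with a density-based cohesion merging rule, and a
    finite Gaussian mixture algorithm built on modified component-wise EM
    with Dirichlet-prior weight annihilation. Every clustering recorded
    during the split/merge loop is scored by a two-part minimum-message-length
    criterion and the shortest code wins. The package also ships simulators
    for QPSK constellation data, overlapping Gaussian mixtures, state-based
    gene-expression profiles and periodic cell-cycle expression, together
    with external (ARI, NMI, Jaccard, correct-selection rate) and internal
    (silhouette, Calinski-Harabasz) validation indices and a replication
    harness for the simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'core.R'
    'mml.R'
    'cem2.R'
    'cohesion.R'
    'io.R'
    'methods.R'
    'metrics.R'
    'optoc.R'
    'simulate.R'
    'smart.R'
    'replicate.R'
    'smartclust-package.R'
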