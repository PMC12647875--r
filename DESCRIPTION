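Package: neuroepochs
Title: Turning Points and Epochs in Lifespan Connectome Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for charting how the topology of structural brain networks
    changes across the human lifespan. The package takes subject-level
    streamline-count connectivity matrices through density-targeted
    thresholding and weight normalization, computes a suite of weighted
    graph-theory measures (integration, segregation and centrality), embeds
    age-averaged metric profiles with an ensemble of UMAP projections, and
    detects major topological turning points as density peaks over the
    ensemble's polynomial-trajectory inflections. The resulting lifespan
    epochs are characterized with within-epoch correlations, LASSO age
    prediction, principal components with parallel analysis, Welch/Games-
    Howell comparisons and dynamic time warping of score trajectories. A
    synthetic-cohort generator with planted trajectories makes every stage
    testable without access to restricted imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    glmnet,
    uwot,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
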