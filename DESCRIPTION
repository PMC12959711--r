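Package: connectomeIB
Title: Interpretable Information-Bottleneck Graph Learning and Subtyping for
    Functional Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control classification of functional-connectivity
    brain graphs with an interpretable information-bottleneck graph neural
    network, and for density-peaks subtyping of the learned graph embeddings.
    Includes Fisher-z connectivity matrices and top-percentile graph
    construction, leakage-safe empirical-Bayes ComBat harmonization of
    multisite edge data, matrix-based Renyi alpha-order entropy and mutual
    information on RBF Gram matrices, a GIN encoder with concrete-relaxed
    edge masks and bilinear second-order pooling, nested cross-validation and
    leave-one-site-out protocols, density-peaks clustering with bootstrap and
    permutation stability statistics, PCA plus leave-one-out ridge regression
    for brain-symptom association, and a synthetic multisite benchmark
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
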