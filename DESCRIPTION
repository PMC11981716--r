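Package: catmixvi
Title: Variational Bayesian Mixture Models and Consensus Clustering for Categorical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian finite mixture models to categorical (including
    binary) data by coordinate-ascent variational inference. The mixture is
    deliberately overfitted (a symmetric Dirichlet weight prior with
    concentration below one empties superfluous components), so the number of
    non-empty clusters estimates the true number of clusters. An optional
    feature-saliency layer performs variable selection simultaneously with
    clustering: each variable either follows cluster-specific categorical
    parameters or a shared null model. Because variational optima depend on
    initialisation, the package also provides model averaging: many
    independently initialised fits are combined through an observation-by-
    observation co-clustering matrix, summarised into a single consensus
    partition (Medvedovic agglomeration or minimisation of the expected
    variation of information) and a consensus selected-variable set obtained
    by thresholding across-run selection proportions. Includes a synthetic
    data generator with planted cluster structure and noise variables,
    experiment orchestration, and matrix-of-clusters construction for
    integrative (cluster-of-clusters) analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
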