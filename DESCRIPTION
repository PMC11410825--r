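Package: ppifuse
Title: Sequence- and Ontology-Based Protein-Protein Interaction Prediction
    with Hybrid Score Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interactions from amino-acid sequences
    and Gene Ontology annotations. Proteins are encoded on fourteen
    physicochemical scales and compressed to fixed-length auto-covariance
    vectors; pair-level ontology features are built from lowest-common-ancestor
    clusters of the GO directed acyclic graph, augmented by a chaotic-weight
    semantic-similarity score. Two predictors trained from scratch (a
    single-cell LSTM recurrent network and a deep belief network of stacked
    restricted Boltzmann machines) are combined by score-level fusion with
    MAPE-derived weights, and the fusion weights are tuned by a hybrid
    shark-smell/Aquila metaheuristic (AISSO) against a mean-squared-error
    objective. Includes a synthetic-data generator with planted interaction
    signal, evaluation metrics, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
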