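Package: survnnet
Title: Neural-Network Cox Proportional-Hazards Models with Two-Stage
    Multi-Modal Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Survival prediction with shallow neural networks trained by
    maximizing the Cox partial likelihood. A single hidden layer feeds a
    proportional-hazards output node; regularization combines node dropout
    with an L2 penalty chosen by grid search under k-fold cross-validation.
    Hidden-node activations from per-modality models (for example
    histopathology image features and gene expression) can be fused and fed
    to a second-stage network for multi-modal prognosis prediction. Includes
    Harrell's concordance index with the literal pair-counting convention,
    Kaplan-Meier / log-rank risk-group evaluation, mean-substitution feature
    importance, a histopathology tile-selection and channel-normalization
    front end, image-gene association graphs, and simulators for
    proportional-hazards survival data with planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
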