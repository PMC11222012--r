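Package: drivernet
Title: Brain-Network Recognition of Distracted Driving States from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs functional brain networks from multichannel EEG and
    recognizes normal, cognitively distracted, and visually distracted driving
    states. Signals are band-limited (delta, theta, alpha, beta) by wavelet
    packet or FIR decomposition; pairwise synchronization is estimated with
    synchronization likelihood (SL), phase locking value (PLV), and
    magnitude-squared coherence (COH); binary graphs over a sparsity sweep
    yield global topology features (characteristic path length, clustering
    coefficient, global and local efficiency) aggregated as area under the
    sparsity curve; feature tables feed k-nearest-neighbour, random forest,
    gradient boosting and support vector machine classifiers with
    cross-validated evaluation; state contrasts are tested by one-way ANOVA
    with Bonferroni correction. Includes a seeded generator of coupled
    narrowband cohorts so the full pipeline is testable end-to-end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    xgboost,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
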