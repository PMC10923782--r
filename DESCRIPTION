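Package: optoMPC
Title: Deep Model Predictive Control of Single-Cell Optogenetic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico platform for receding-horizon (model predictive)
    control of optogenetic gene expression in single bacterial cells. Provides
    a stochastic mother-machine cell simulator emitting 8-feature single-cell
    timeseries under binary red/green light actuation; a recurrent (LSTM)
    encoder / multi-layer perceptron decoder forecaster that compresses a
    cell's variable-length past into a 32-dimensional latent vector and
    predicts fluorescence over a 1-4 h horizon; linear-regression and
    ODE + hybrid Kalman filter baseline predictors; a binary particle swarm
    optimizer with an exhaustive-search oracle for strategy selection; and
    an evaluation toolkit (per-cell and per-timepoint RMSE, growth-rate
    computation with artifact filters, growing-fraction partitioning,
    missing-value-aware smoothing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    Matrix,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
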