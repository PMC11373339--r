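Package: pepimpute
Title: Peptide-Level Missing-Value Imputation with Graph Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Imputation of missing peptide abundance values in label-free bottom-up
    mass-spectrometry proteomics. Implements an attention-based graph neural network
    that fuses peptide abundance profiles, amino-acid sequence embeddings and the
    peptide-peptide graph induced by shared parent proteins, predicting a Gaussian
    mean and variance per missing value so that every imputation carries an
    uncertainty estimate. Ships eleven classical comparison imputers (minimum-value,
    median, k-nearest neighbours, chained-equation ridge regression, random forest,
    iterative SVD, Bayesian PCA, denoising and variational autoencoders,
    collaborative filtering), a benchmarking framework with sample-wise RMSE,
    paired signed-rank method comparison and differential-expression ROC analysis,
    and a fully seeded synthetic-data generator that reproduces the correlation and
    missingness structure of peptide tables for testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    optparse,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
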