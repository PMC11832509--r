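Package: sembeddings
Title: Pre-Data Screening of Questionnaire Measurement Models from Item
    Embedding Similarities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits confirmatory factor analysis (CFA) measurement models to
    cosine-similarity matrices of questionnaire-item embeddings, treating the
    similarity matrix as a pseudo-correlation matrix with a nominal sample
    size, so that model misfit can be detected before any data collection.
    Provides a maximum-likelihood covariance-structure engine with CFI, TLI,
    SRMR and RMSEA fit indices and score- and refit-based modification
    indices; wrong-model and unidimensionality screening batteries; agreement
    statistics between similarity-derived and empirical correlation matrices;
    and a synthetic-instrument simulator with Likert discretization and
    controlled-fidelity pseudo-similarity matrices for validating the whole
    pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
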