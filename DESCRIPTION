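Package: vocanet
Title: Partial-Correlation Network Analysis of Anxiety and Acoustic Voice Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking state anxiety to acoustic speech
    parameters through regularized partial-correlation networks. Extracts five
    voice biomarkers (local jitter, fundamental frequency, the F1/F2 formant
    ratio, frame-averaged intensity, and speech rate) from mono WAV recordings;
    summarises low- versus high-anxiety groups with pooled t-tests and Cohen's
    d; estimates sparse Gaussian graphical models from Spearman correlations by
    graphical lasso with extended-BIC model selection; quantifies edge accuracy
    and centrality stability by nonparametric and case-dropping bootstrap; and
    compares group networks with a permutation-based network comparison test.
    A source-filter vowel synthesizer and a planted-network feature-table
    generator provide ground-truth inputs so every stage is testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
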