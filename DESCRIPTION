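Package: wbnet
Title: Wavelet-Based Functional Brain Network Construction and Method
    Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds frequency-band-specific functional brain networks from
    regional time series using discrete and maximal-overlap discrete wavelet
    transforms (DWT/MODWT) under the Daubechies Extremal Phase, Least
    Asymmetric, and Coiflet orthonormal filter families, and provides the
    machinery to compare those methodological choices: scale-wise wavelet
    correlation (and partial correlation) matrices, density thresholding,
    graph summaries (clustering, path length, efficiencies, Louvain
    modularity with consensus partitions), a statistics battery
    (length-variation statistic, paired and two-sample t tests, sign tests
    with family-wise correction, repeated-measures ANOVA, -log10 p
    sensitivity surfaces), boosted decision-tree classification under
    cross-validation, and a synthetic two-group cohort generator with
    long-memory (fractional Gaussian noise) community-structured signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
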