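Package: fddlm
Title: Fractional-Dynamics Feature Extraction and Deep-Learning Staging of
    COPD Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for staging chronic obstructive pulmonary disease (COPD)
    from multichannel physiological recordings. Implements focus-based
    multifractal detrended fluctuation analysis (scaling functions, focus
    points, generalized Hurst exponents, group confidence bands and
    Wasserstein comparison of H(q) curves), identification of discrete
    fractional-order coupled dynamics under the Grünwald-Letnikov operator
    (per-channel order estimation, coupling-matrix least squares, alternating
    estimation with unknown low-dimensional inputs, convergence studies), and
    a feedforward softmax classifier on flattened coupling matrices with
    k-fold, institution hold-out and reduced-channel transfer evaluation
    protocols. Includes exact synthetic generators (fractional Gaussian noise
    by circulant embedding, binomial multiplicative cascades with analytic
    generalized Hurst exponents, fractional coupled systems, staged cohorts)
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    nnet,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
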