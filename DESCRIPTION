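Package: fcsnet
Title: Decision Bias and Directed Beta-Band Connectivity in a
    Fronto-Cingulo-Striatal Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for approach-avoidance decision experiments with
    simultaneous multi-region local field potential (LFP) recordings. Fits
    conditional-logit choice models and cost-benefit ratios, builds smoothed
    decision matrices and quantifies stimulation-induced choice shifts with
    pointwise Fisher exact tests, extracts beta-band (13-30 Hz) power responses
    with multitaper spectra and pink-noise baselines, embeds beta-response
    matrices by correlation-distance multidimensional scaling with
    BIC-selected Gaussian-mixture clustering, estimates coherence and
    frequency-domain (Geweke) Granger causality with a directional asymmetry
    index over 5-30 Hz, and classifies single-unit task correlates. A
    synthetic-data generator produces choice sessions and coupled oscillatory
    LFP networks with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mclust,
    jsonlite
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
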