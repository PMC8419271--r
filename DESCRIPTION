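Package: pcn
Title: Higher-Order Brain Functional Networks by Iterated Pearson Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates brain functional networks (BFNs) from ROI-level fMRI
    time series by Pearson correlation and iterates the correlation operation
    ("correlation's correlation") to obtain the PC^n sequence of higher-order
    networks, tracking its empirical convergence to a binary sign matrix.
    Includes convergence diagnostics (numerical rank, sign changes,
    fixed-point residuals), a subject-level cross-validated classification
    protocol over edge-weight features (two-sample t-test selection, linear
    support vector machine, probability fusion of low- and higher-order
    networks), and a synthetic ROI time-series generator with controlled
    two-group covariance structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
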