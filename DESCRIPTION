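Package: neurocx
Title: Nonlinear Complexity Analysis of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates multichannel resting-state EEG cohorts with
    group-graded fractal complexity (an exact circulant-embedding
    fractional-noise engine plus an alpha rhythm), extracts fixed 5-s
    epochs, and computes Higuchi's fractal dimension, sample entropy and
    Welch band power per electrode and epoch.  Reproduces the group-level
    statistical chain used in clinical EEG complexity studies: log10
    normalisation, one-way ANOVA with Bonferroni-corrected post hoc tests
    globally and per electrode, and PCA separability of the feature
    ensemble.  Includes EDF and CSV recording I/O and a reproducible
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
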