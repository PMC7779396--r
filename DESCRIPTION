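Package: cpmr
Title: Connectome-Based Predictive Modeling of Symptom Severity from
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts a continuous behavioural or clinical score from
    whole-brain functional connectivity matrices using connectome-based
    predictive modeling (CPM): Fisher z-transformed Pearson connectivity,
    Spearman edge selection at a p-value threshold, signed network-strength
    summarisation, linear models under leave-one-out cross-validation, and
    permutation-based inference. Includes node time-series preprocessing
    (motion scrubbing, detrending, nuisance regression, band-pass
    filtering), anatomical summarisation of predictive networks over
    macroscale regions and canonical networks, linear-kernel support vector
    regression and classification comparators, and a synthetic cohort
    generator with planted score-correlated edges for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
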