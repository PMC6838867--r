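Package: rehabdist
Title: Distance-Based Neurorehabilitation Evaluation from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds region-wise functional-connectivity networks from ROI
    time series (or 4D functional images plus an integer-labeled atlas),
    selects group-discriminative edges with a mass-univariate two-sample
    t-test filter, trains a soft-margin linear support vector machine
    separating patients (+1) from healthy controls (-1), and scores every
    longitudinal session by its signed L2 distance to the separating
    hyperplane. Includes the full validation protocol (leave-one-out
    cross-validation metrics, label-permutation significance, 2-means
    clustering checks, paired parametric and non-parametric intra-group
    tests, normalized trajectory comparison against clinical scores) and a
    seeded synthetic connectome cohort simulator with planted edge effects
    and longitudinal recovery drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    MASS,
    Matrix,
    RNifti,
    stats,
    utils
Suggests:
    kernlab,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
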