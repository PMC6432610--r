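Package: vactig
Title: Video-Based Actigraphy for Infant Wake-Sleep Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying wake and sleep states in infants from
    video-derived movement signals (video-based actigraphy). Implements
    recursive-search block-matching motion estimation over grayscale frame
    sequences, two per-epoch features (the mean activity count mACT and the
    burst-proximity feature pSLP), a two-class Bayesian linear discriminant
    classifier with equalized priors, leave-one-subject-out cross validation
    with confusion-matrix metrics, Cohen's kappa and ROC/AUC, and a seeded
    synthetic infant-cohort generator (hypnograms, state-conditional
    actigraphy, and rendered test frames with ground-truth displacements) so
    the whole pipeline can be exercised without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    zoo,
    withr,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    jsonlite
Config/testthat/edition: 3
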