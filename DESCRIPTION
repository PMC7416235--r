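Package: circleEMD
Title: Circular Empirical Mode Decomposition and Task-State Pattern
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Empirical mode decomposition (EMD) for spatial signal vectors
    whose channel sequence is closed into a ring, so that envelope splines
    satisfy periodic continuity conditions and boundary (end-effect)
    distortion vanishes.  Provides the periodic cubic-spline envelope
    machinery, the sifting loop, a classic (non-periodic) EMD baseline for
    end-effect comparison, FFT characterisation of intrinsic mode functions,
    a multi-run fMRI-style preprocessing pipeline (hemodynamic shift, ROI and
    t-value channel selection, outlier clipping, detrending, baseline
    normalisation, spatial z-scoring), three classifiers (RBF-kernel SVM,
    multinomial logistic regression, and a small feed-forward network with
    dropout and batch normalisation) under run-wise 10-fold cross-validation,
    and synthetic-data generators that emulate the multi-run rock/scissors/
    paper study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    nnet,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
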