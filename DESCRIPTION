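Package: hippotex
Title: Hippocampal MRI Texture and Latent Disease-Time Modelling Across the
    Alzheimer's Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 3D region-of-interest MRI texture along the
    Alzheimer's disease continuum. Implements first-order, grey-level
    co-occurrence (GLCM) and grey-level run-length (GLRLM) texture features on
    masked volumes with mu +/- 3 sigma trimming, z-normalisation and 32-bin
    discretisation; PCA feature reduction trained on cognitively unimpaired
    baselines; cross-sectional mixed-effects group comparisons with Holm
    correction and Cohen's f/d effect sizes; a multivariate nonlinear
    mixed-effects spline model that aligns subjects on a latent disease time
    via fixed and random time shifts; spline trajectory models over disease
    time with BIC degree-of-freedom selection, abnormality and
    sensitivity-to-change scales; dual-timescale age-by-disease models; and
    bootstrap comparison of nested regressions predicting cognitive decline.
    A synthetic-cohort and 3D phantom generator makes the full pipeline
    testable without access-controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    lmerTest,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
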