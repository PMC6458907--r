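Package: painpattern
Title: Between-Subject Multivariate Decoding of Evoked fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for between-subject multivariate pattern analysis (MVPA) of
    evoked fMRI responses within a region-of-interest such as the "pain matrix":
    binary-mask algebra (union, intersection, erosion, seeded subsampling,
    nearest-neighbour resampling, left/right splits), first-level preprocessing
    (motion regression, linear detrending and z-scoring, Gaussian smoothing,
    peak-volume pattern extraction, GLM beta maps), psychophysical saliency and
    intensity matching with JZS Bayes-factor validation, ROI-wise univariate
    comparisons with max-statistic sign-flip permutation correction, and
    leave-one-subject-out linear support-vector classification with
    permutation-test null distributions, sensitivity maps, consistent-sign maps
    and cross-dataset generalization. A synthetic-data generator emulating
    event-related and blocked stimulation designs makes the whole pipeline
    testable end to end without access to human imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
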