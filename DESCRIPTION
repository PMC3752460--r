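Package: rsndr
Title: Group-ICA Dual Regression with Inter-Component Permutation Inference
    for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state functional-connectivity group analysis:
    temporal-concatenation group spatial ICA with Gaussian/gamma mixture-model
    thresholding of component maps, two-stage dual regression (with and without
    time-course variance normalization), and group-difference inference by
    threshold-free cluster enhancement (TFCE) with max-statistic permutation
    correction, including joint correction across components by y-concatenation
    and a voxel-wise gray-matter covariate handled by Freedman-Lane residual
    permutation. Includes a synthetic resting-state cohort generator with
    planted network amplitude differences and focal atrophy, used to validate
    error control and power of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
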