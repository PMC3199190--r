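Package: permfmri
Title: Fast Random Permutation Inference for Single-Subject fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric, familywise-error-corrected activation mapping for
    single-subject fMRI. Surrogate null datasets are generated by cubic
    detrending, voxelwise autoregressive (Yule-Walker) whitening with spatially
    pooled parameters, random permutation of the whitened series, and inverse
    whitening; spatial smoothing and the detection statistic (GLM t-test or
    restricted canonical correlation analysis with adaptive spatial filters)
    are applied inside every permutation. Corrected thresholds and p-values are
    read off the null distribution of the maximum statistic, with Bonferroni
    and random-field-theory thresholds provided for comparison, Ljung-Box
    whiteness diagnostics, and a synthetic fMRI generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
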