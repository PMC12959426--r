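Package: lfdwi
Title: Trace Diffusion-Weighted Imaging and Lesion Detection at Low Field
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for multi-direction
    diffusion-weighted MRI at low magnetic field. Provides a diffusion-tensor
    brain phantom with anisotropic white-matter tracts and ischemic lesions,
    Rician-noise signal simulation for single-direction and three-direction
    acquisitions, trace DWI and apparent diffusion coefficient (ADC) map
    synthesis with 12-parameter affine coregistration and isotropic
    resampling, region-wise signal-uniformity statistics, and
    lesion-detection diagnostic accuracy (ROC with Youden cut points, exact
    binomial confidence intervals, Fleiss kappa with bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
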