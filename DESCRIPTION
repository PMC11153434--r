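Package: conseg
Title: Consensus-Contour PET Radiomics with Robustness and Accuracy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates PET lung-tumor phantoms with known ground truth,
    delineates them with four automatic segmentation methods (41% SUVmax
    thresholding, contrast-oriented thresholding, affinity propagation
    clustering, and a region-based active contour) under rectangular or
    irregular initial masks, fuses the results into a consensus contour by
    voxel-wise majority vote, extracts the standard 107-feature radiomic
    catalog (shape, first order, GLCM, GLRLM, GLSZM, NGTDM, GLDM) on
    fixed-bin-width SUV discretization, and quantifies per-feature
    robustness and accuracy with single-measure absolute-agreement
    intraclass correlation coefficients, category summaries, and Spearman
    feature-correlation clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
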