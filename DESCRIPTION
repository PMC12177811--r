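Package: tractcrowd
Title: Along-Tract White-Matter Statistics with TFCE Permutation Inference
    and Cognitive Crowding Models
Version: 0.1.0
Authors@R:
    person("Tract", "Maintainer", email = "maintainer@tractcrowd.dev",
           role = c("aut", "cre"))
Description: Sectional (along-tract) analysis of diffusion-MRI fiber bundles:
    streamline I/O (TCK, TRK, NIfTI-1 scalar maps), ROI-based bundle
    dissection, one-class-SVM outlier removal, ICP alignment of hemispheric
    bundles, joint 1-D ISOMAP parameterization with core extraction and
    binning, skeleton-normalized scalar profiles, bin-wise Mann-Whitney
    comparisons with threshold-free cluster enhancement (TFCE) and
    max-statistic permutation family-wise error correction, Barnard's
    unconditional exact test, verbal/performance-IQ crowding classification
    and logistic crowding models, plus a synthetic cohort generator for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    data.table,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
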