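Package: porindex
Title: Porosity Index and Bone Mineral Density Analysis for Quantitative
    CT and Dual-Echo UTE MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-wise pipeline relating quantitative CT derived bone
    mineral density (BMD) to the ultra-short echo time (UTE) MRI porosity
    index (PI) in whole bones. Calibrates CT grey values to a BMD scale
    against hydroxyapatite phantom inserts, computes PI maps from dual-echo
    UTE acquisitions, segments bone with a median / local-threshold /
    connected-component chain, aligns PI to CT with multi-resolution affine
    mutual-information registration, and runs per-specimen voxel-wise
    regression with study-level group statistics. Includes a synthetic
    condyle generator with a two-pool bone water T2* signal model for
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
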