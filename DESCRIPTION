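Package: doseatlas
Title: Voxel-Based Dosimetric Analysis of Radiotherapy Dose in Template Space
Version: 0.1.0
Authors@R: person("doseatlas", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for voxel-based analysis of radiotherapy dose
    distributions in a common (MNI-like) template space: NIfTI volume
    handling, synchronized spatial normalization of planning CT and dose
    volumes (rigid, affine and demons-style nonlinear registration under a
    sum-of-squared-differences objective), group dose mapping by dose
    sub-range, voxel-wise two-sample GLM comparison of delivery techniques
    with threshold-free cluster enhancement (TFCE) and permutation
    family-wise-error inference, and atlas-labelled cluster reporting.
    Includes a digital head-phantom cohort simulator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
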