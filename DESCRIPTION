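Package: llmseg
Title: Hippocampus Segmentation by Local Linear Mapping of Patch Distance Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based segmentation of compact brain structures (the hippocampus)
    from T1-weighted MR volumes by local linear mapping (LLM). Training MR/label
    pairs are converted to signed Euclidean distance fields, MR and distance-field
    patches are compressed into a paired dictionary by k-means clustering, test
    patches are coded over their k nearest MR atoms by locality-constrained linear
    coding (LLC) or local anchor embedding (LAE), the coding weights are transferred
    to the paired distance-field atoms, and overlapping patch predictions are fused
    by a confidence-based weighted average whose weights decay with the coding
    residual. Includes NIfTI volume handling, an exact 3D signed Euclidean distance
    transform, a synthetic phantom generator for controlled experiments, and Dice
    overlap evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
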