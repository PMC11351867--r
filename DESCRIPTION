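Package: icseg
Title: Interactive Cascaded Lesion Segmentation with Automated Quality Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-to-fine interactive segmentation framework for
    multi-channel image slices (e.g. multiparametric MRI of prostate
    lesions). A coarse encoder-decoder network with squeeze-and-excitation
    and non-local attention produces an initial probability map; a
    regression "rejection" network predicts the Dice quality of that
    result; a threshold gate routes each slice either to simulated manual
    bounding-box prompts or to boxes derived from the coarse mask; and a
    prompt-conditioned fine network produces the final segmentation.
    Includes a seeded multi-channel phantom generator, NIfTI input/output,
    desk-scale CPU training for all three networks, threshold-sweep
    analysis of the workload/accuracy trade-off, and evaluation metrics
    (Dice, 95th-percentile Hausdorff distance, lesion-level detection
    scores, R-squared, rejection ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
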