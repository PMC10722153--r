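Package: graspmvpa
Title: Simulated Event-Related BOLD Data and ROI-Based Orientation Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for region-of-interest multivoxel pattern analysis of
    grasp-related fMRI experiments, paired with an event-related BOLD
    simulator with known ground truth. Implements the experimental design
    layout (four action conditions by two object orientations, three trial
    phases), a double-gamma HRF convolution generator with AR(1) noise and
    polynomial drift, motion-based run exclusion, percent-signal-change
    univariate summaries, contrast-based top-k voxel selection, fold-wise
    z-scoring, linear support vector machine decoding with leave-one-run-out
    cross-validation, cross-condition transfer decoding, cross-phase
    decoding, and group-level inference with Benjamini-Hochberg false
    discovery rate correction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
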