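Package: cineheart
Title: Supervised and Semi-Supervised Whole-Heart Segmentation of 4D Cine
    Cardiac MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Multi-structure segmentation of time-resolved (3D + time) cine
    cardiovascular magnetic resonance images covering the whole heart and
    great vessels.  Provides a compact 3D U-Net with hand-written
    backpropagation, a cyclic label-propagation scheduler that grows two
    annotated cardiac phases (end-diastole and end-systole) into
    pseudo-labels for every frame of the cardiac cycle, certainty-weighted
    probabilistic training, a deformable beating-heart phantom generator
    with analytic ground truth, and an evaluation suite (per-structure Dice
    overlap, chamber volume curves, ejection fraction, paired statistical
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
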