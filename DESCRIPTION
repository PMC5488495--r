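Package: cellpath
Title: Semisupervised Cell Detection on Extremal-Region Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cells in 2-D microscopy images from dot annotations
    alone. Candidate cells are the extremal regions of a component
    (max-) tree built on the intensity image or on a learned pixel
    probability map. A one-hidden-layer perceptron scores each region;
    it is trained by maximum a posteriori estimation combining a
    supervised quadratic loss on dot-derived region labels with a
    differentiable unsupervised path-consistency loss (a relaxed
    disjunctive normal form enforcing at most one cell per
    root-to-leaf path), with closed-form updates for the two Gaussian
    noise scales. Final non-overlapping detections are selected by an
    exact bottom-up/top-down dynamic program on the tree (a greedy
    per-path alternative is provided). Includes a synthetic scene
    generator with ground-truth dots and instance masks, a random
    forest pixel classifier on a multi-scale filter bank, Hungarian
    detection matching with precision/recall/F-score and DICE
    evaluation, and a benchmark harness comparing supervised-only and
    semisupervised training arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    clue,
    jsonlite,
    ranger,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
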