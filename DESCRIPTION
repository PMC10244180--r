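Package: ovipost
Title: Quantitative Analysis of the Drosophila Egg-Laying Behavioral Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative study of the Drosophila oviposition
    behavioral sequence from frame-wise ethogram annotations, pose-estimation
    keypoint tracks and paired calcium-imaging recordings. Implements
    start-to-start behavioral transition matrices with one-sided permutation
    significance, first-occurrence ordering and event-aligned behavior time
    courses; burrow-episode segmentation with cycle statistics and egg
    output/depth/drop summaries; optogenetic post-expulsion outcome
    classification; a 17-channel kinematic and Morlet-wavelet feature
    extractor with a velocity-threshold walking classifier; unsupervised
    behavior mapping by t-SNE embedding, kernel-density watershed
    segmentation and event-aligned cluster significance; a calcium pipeline
    with median-baseline dF/F0, tracked-distance normalization, total
    variation event detection and 3-s integral normalization; frame-wise
    annotator agreement (precision/recall/F1); and seeded synthetic-data
    generators with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    MASS,
    Rtsne,
    FNN,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
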