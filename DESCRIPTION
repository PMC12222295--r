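Package: gliaScore
Title: Scoring of Neuroglial Cells in Fluorescence Microscopy Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An open, testable pipeline for morphometric scoring of
    neuroglial cells in multi-channel immunofluorescence images of brain
    tissue. Z-stacks are collapsed to maximum-intensity projections;
    scribble-trained per-pixel classification separates stained objects
    from background per channel; small pixel groups are suppressed and
    per-channel area fractions measured. Microglia are detected by a
    dual-channel criterion (a nucleus-channel blob ringed by
    microglia-channel signal), their processes are counted in an annular
    zone of influence around each nucleus, and cells are assigned to
    activity states (ramified, hyper-ramified, bushy, amoeboid) from the
    relative area of the nucleus via confidence-interval-merged class
    limits. A synthetic-scene generator with planted ground truth makes
    every stage testable without microscope data, and a study-statistics
    layer aggregates per-image metrics to per-mouse means and compares
    experimental groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    randomForest,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: ImageAnalysis, CellBiology, Classification, Software
RoxygenNote: 7.3.3
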