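Package: rppgpatch
Title: Heart Rate from Facial Video via Adaptive Triangular Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Remote photoplethysmography (rPPG) toolkit that recovers heart
    rate from facial video. Facial landmarks are connected by a Delaunay
    triangulation into local patches, non-skin patches are removed with a
    naive-Bayes skin-chromaticity model in Cb-Cr space, size-unstable patches
    are rejected by the interquartile range of their normalized pixel-count
    change series, and the pulse frequency is voted from pairwise FastICA
    decompositions of per-patch green-channel traces. Includes a joint face
    detection and alignment initializer (cascaded random forest over
    shape-indexed pixel-difference features), a synthetic facial-scene
    generator with known embedded pulse for end-to-end validation, and the
    standard agreement metrics (RMSE, Bland-Altman limits, well-estimation
    rate, spectral SNR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    png,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
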