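Package: feedmark
Title: Quantification of Insect Feeding Behavior from Time-Lapse Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated quantification of leaf herbivory from time-lapse
    scans of caged leaves. Segments leaves by color thresholding, removes
    insect-body false positives by cumulative time-difference masking,
    measures per-cage leaf area over time, detects feeding events as peaks in
    the leaf-area loss rate, computes per-event behavioral parameters
    (area consumed, duration, rate, inter-event interval), compares groups of
    assays with Welch's t-test, and maps the spatio-temporal pattern of
    feeding marks (per-event consumed regions, centroids, and inter-mark
    distances). Includes a scripted synthetic time-lapse generator with
    ground truth so every stage can be validated without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    jpeg,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
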