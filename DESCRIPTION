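Package: finprint
Title: Photo-Identification of Blue Whale Dorsal Fins from Reduced SIFT
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies blue whale dorsal fin photographs into six shape
    classes (right/left falcate, hooked, triangular) using a reduced
    Scale Invariant Feature Transform: difference-of-Gaussians keypoints
    pruned by a standard-deviation threshold on the scale stack,
    orientation-histogram descriptors, and a nearest-centroid
    (median-estimation) classifier with a K-nearest-neighbour baseline.
    Includes specificity/sensitivity/accuracy and ROC/AUC evaluation,
    a synthetic dorsal-fin image generator with ground-truth contours
    for testing without a photo database, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jpeg,
    tiff,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
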