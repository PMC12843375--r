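Package: kyphometry
Title: Automated Thoracic Kyphosis Morphometry from Vertebral Centroids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Circle-fit estimation of the thoracic kyphosis angle from
    Th4-Th12 vertebral centroids on lateral spine images, with
    Cobb-equivalent conversion, quality-control flagging and threshold
    classification. Includes a synthetic spine-phantom generator with known
    ground truth (centroid chains, raster renderings, simulated manual
    observers), a classical blob detector with a full object-detection
    evaluation harness (IoU matching, precision/recall/F1, mAP, mean IoU),
    and the method-agreement statistical protocol comparing automated and
    manual angles (Pearson r, ICC(A,1), Lin's CCC, error metrics,
    Bland-Altman limits of agreement, threshold diagnostics with Wilson
    intervals, ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
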