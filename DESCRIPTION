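Package: plotsieve
Title: Feature-Combination Mapping of Fragmented Crop Plots from UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting fragmented cultivation plots (such as Ligusticum
    chuanxiong fields) from consumer-grade UAV RGB orthomosaics and the digital
    elevation model produced alongside them. The package builds a 41-layer feature
    space (12 visible-band color indices, 24 gray-level co-occurrence texture
    statistics, 4 HSV/HLS color components, and elevation), screens features by
    Pearson correlation and an interclass difference score, enumerates feature
    combinations, classifies them with pixel-based (maximum likelihood, SVM) and
    object-based (multiresolution segmentation with KNN and SVM) workflows, and
    ranks the combinations with a five-metric composite score backed by 5-fold
    cross-validation, one-way ANOVA and Tukey HSD tests. A synthetic scene
    generator provides reproducible test landscapes with controllable spectral,
    textural and elevation class signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    jsonlite,
    yaml,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
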