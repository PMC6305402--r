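Package: icFeatures
Title: Data-Driven Discovery of Spatial Immune-Contexture Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Systematic enumeration and computation of density-, distance-,
    and heterogeneity-based spatial features over annotated cell point data
    from histological slides (Ki67, CD4 and CD8 compartments), plus folded
    ROC-AUC and overall-performance-measure (OPM) ranking of features for
    binary endpoints such as MSI vs MSS, significance assessment against
    pseudo-random feature matrices, and a constrained synthetic-slide
    generator for end-to-end verification without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    pracma,
    parallel,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Spatial, SingleCell, FeatureExtraction, Classification
RoxygenNote: 7.3.3
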