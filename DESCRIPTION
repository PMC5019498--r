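Package: landrefugia
Title: Climate-Driven Landcover Distribution Modelling and Refugia Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to model the geographic distribution of native landcover
    under current and future climate and to map climate-stable refuges.
    Grid cells are partitioned into climatically coherent groups with a
    cross-validated classification tree; each group ("leaf") is treated as
    a pseudo-species and its distribution is fitted with a suite of
    envelope, statistical and machine-learning distribution models,
    combined into TSS-weighted ensembles, projected onto future climate
    scenarios from several pseudo-GCMs, and reduced to a cross-model
    consensus. Stability (refuge) maps, range areas, centroids and
    displacement vectors summarise the predicted change. A synthetic-world
    generator with known climate-vegetation rules makes the whole pipeline
    testable end to end with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    randomForest,
    mgcv,
    glmnet,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
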