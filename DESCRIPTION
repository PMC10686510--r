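Package: ffsmatrix
Title: Furniture Fire-Safety Matrix: Relative Fire Risk and Flame-Retardant Exposure Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores furniture product types for relative fire risk (injury and
    property damage) and relative chemical flame-retardant (CFR) exposure
    potential from structured evaluator questionnaires. Fire risk follows a
    failure-chain model aggregated by the lowest quartile of dimension scores;
    exposure potential is an equally weighted arithmetic mean. The two models
    are reconciled by ranking, quadrant classification on the injury-exposure
    plane, and agglomerative Euclidean clustering with a dendrogram cut, and
    stress-tested by systematic-error sensitivity imputation on contact scores
    and external-evaluator comparison. Includes a synthetic-data generator
    with known ground truth (latent archetype profiles, evaluator noise,
    planted clusters) and packaged fixtures of the study's printed score and
    panel-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
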