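Package: itemreduce
Title: Data-Driven Reduction of Diagnostic Item Sets via Random-Forest
    Importance, Youden Thresholding and McNemar Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for deciding how few items of a clinical diagnostic
    instrument are enough. Subject-by-item tables of ordinal codes (such as
    ADOS module 3/4 observations or ADI-R algorithm items) with a binary
    best-estimate clinical label are recoded, split into training and
    validation parts, and ranked by repeated cross-validated random-forest
    permutation importance (mean decrease in accuracy on held-out folds).
    Nested reduced-feature forests are trained for every prefix of the
    ranking, each with a Youden-index optimal threshold; an "optimal" model
    is chosen by a parsimony-weighted score over scaled AUC and model
    complexity, and a "minimal" model is identified as the smallest feature
    set whose validation-set classification errors do not differ from the
    full-feature model under McNemar's test. A latent-Gaussian synthetic
    cohort generator with planted informative items makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
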