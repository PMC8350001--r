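Package: itaml
Title: Iterative Thematic Analysis of Wide Survey Data with Regularized Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers correlates of a rare binary outcome in wide
    demographic-survey data by iterating staged regularized logistic
    models. A lasso (L1) stage screens thousands of one-hot encoded
    survey features, a ridge (L2) stage ranks the survivors by
    coefficient magnitude, and a discrete-curvature knee point cuts the
    ranked curve. Selected features are grouped into analyst-declared
    themes; the dominant theme is dropped and the models are refit until
    explicit stopping rules fire (iterative thematic analysis). Includes
    imbalance-aware evaluation (balanced error rate and AUC), a
    feed-forward neural network cross-check with permutation importance,
    and a synthetic generator of wide correlated-categorical survey
    tables with planted themed signal for end-to-end validation when the
    real microdata are access-restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
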