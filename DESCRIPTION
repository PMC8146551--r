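Package: gsfts
Title: Gain-Sequence Forward Tabu Search Feature Selection for Clinical
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for imbalanced binary clinical
    outcome prediction. A gradient-boosted-tree classifier built on the
    second-order (Newton) boosting objective supplies gain-based feature
    importance; a sequential forward search over the gain ranking seeds a
    tabu search over bit-string subset encodings with candidate sets, tabu
    tenure and an aspiration rule. Includes an EasyEnsemble wrapper for
    class imbalance, preprocessing (missing-value handling, outlier
    removal, min-max scaling), stratified cross-validation, McNemar paired
    classifier comparison, grid search, baseline selectors (plain forward
    search, recursive feature elimination), and a synthetic clinical
    cohort generator with planted informative features for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
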