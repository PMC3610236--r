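Package: nbcmerge
Title: Naive Bayes Consensus Merger Models for Clinical Risk Prediction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds naive Bayesian classifier "merger models" for binary
    clinical outcomes from mixed-type predictor tables with missing values.
    The pipeline repeatedly partitions a cohort into random training and
    test sets, selects predictors within each training set by greedy
    backward elimination against a leave-one-out objective, pools variables
    chosen in a minimum number of partitions into a consensus candidate
    set, and fits a final model on the full cohort. Evidence strength is
    reported as posterior odds with Jeffreys credibility intervals, and the
    final classifier is benchmarked against six complete-case logistic
    regression strategies. A synthetic-cohort generator with planted
    effects and configurable missingness supports fully reproducible
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
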