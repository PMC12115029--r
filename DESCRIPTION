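Package: eogstress
Title: Stress Detection from Smart-Eyewear Electrooculography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting mental stress from
    electrooculography (EOG) recorded by sensor-equipped eyewear. Provides a
    seedable multi-subject synthetic-session generator with ground-truth blink
    and motion-artifact annotations; Butterworth band-pass / FIR low-pass
    preprocessing with accelerometer-coupled artifact rejection; blink
    detection by template matching with normalized-RMSE scoring and an
    adaptive acceptance threshold; sliding-window extraction of nine
    blink- and signal-statistics features; Lasso feature selection; five
    reference classifiers (random forest, logistic regression, linear SVM,
    decision tree, distance-weighted k-nearest neighbours); and evaluation
    under stratified 10-fold and leave-one-subject-out cross-validation with
    per-class precision, recall, F1 and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
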