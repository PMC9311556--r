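Package: copemd
Title: EMD-Based Classification of Postural Sway for Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating Parkinson's disease from healthy balance
    control using force-plate center-of-pressure (COP) recordings. Signals in
    the medial-lateral and anterior-posterior directions are decomposed into
    intrinsic mode functions by empirical mode decomposition (EMD); three
    temporal and three spectral descriptors are extracted from each signal and
    each mode; the most informative features are selected by random-forest
    importance; subjects are classified with KNN, CART, random forest and SVM
    under stratified 10-fold cross-validation; and the classifier decisions
    are fused by majority vote, a Bayesian rule, and Dempster-Shafer evidence
    combination. A seeded synthetic-cohort generator emulates two-direction
    COP sway with class-dependent spectral content so the whole pipeline can
    be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
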