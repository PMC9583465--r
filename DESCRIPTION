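Package: oscml
Title: Explainable Machine Learning for Respiratory Oscillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating explainable classifiers of
    respiratory disease from forced oscillation technique (FOT) impedance
    spectra. Provides the extended RIC (eRIC) two-compartment circuit model
    of respiratory impedance (forward evaluation, closed-form resonant
    frequency, and bounded Levenberg-Marquardt inversion), extraction of the
    eleven standard oscillometric indexes, a triangular three-set
    fuzzification scheme fitted on training data only, tree-based genetic
    programming and grammatical evolution engines synthesizing interpretable
    classifiers (arithmetic expressions and fuzzy pattern trees), adapters
    for eight off-the-shelf baseline learners, and a nested cross-validation
    harness with grid search, recursive feature elimination and
    feature-importance reporting. A synthetic cohort generator emulates a
    three-group case-control oscillometry study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    glmnet,
    ranger,
    rpart,
    e1071,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
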