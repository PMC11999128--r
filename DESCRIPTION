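Package: dmtransit
Title: Diabetes Progression Staging, Clinical-Note Extraction and Transition Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling diabetes mellitus progression from electronic
    health records. Provides a synthetic EHR cohort generator with ground-truth
    annotations (four-stage discrete-time Markov model of metabolic goals and
    chronic complications, stage-conditional biomarker emission, templated
    clinical notes), a dictionary-based clinical NLP extractor (preprocessing,
    spelling correction, greedy n-gram entity search, bag-of-words vectors,
    rule-based pharmacological-adherence classification), HbA1c goal staging
    with one- and two-year transition matrices, hypoglycemic guideline-adherence
    cross-classification, and a nested binary transition-prediction layer
    (stratified cross-validated model grid, SMOTE resampling, kappa-optimal
    probability cutoffs, marginal effects, and a four-stage probability
    calculator).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rpart,
    class,
    randomForest,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
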