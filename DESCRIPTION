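Package: rewardDFH
Title: Functional Classification of Reward Responsiveness and
    Distance-from-Hyperplane Normative Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a linear max-margin classifier separating parcel-level
    BOLD responses to received reward versus received punishment in a
    typically-developing reference sample, scores individuals by their
    signed distance from the decision hyperplane (DFH), norms reward-
    condition distances against the reference distribution into five
    standard-deviation categories, and runs downstream contingency,
    correlation and symptom-severity analyses. Includes a synthetic cohort
    generator with configurable reward-response attenuation and symptom
    coupling so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'cohort.R'
    'standardize.R'
    'select.R'
    'classifier.R'
    'dfh.R'
    'io.R'
    'stats.R'
    'simulate.R'
    'pipeline.R'
    'rewardDFH-package.R'
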