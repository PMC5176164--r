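Package: sealgram
Title: Behaviour Classification for Otariid Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds behavioural ethograms for fur seals and sea lions from
    tri-axial accelerometer data. Simulates multi-subject, behaviour-labelled
    25 Hz acceleration traces; decomposes them into static and dynamic
    components to obtain ODBA, VeDBA and body orientation; summarises them
    into epoch-level movement statistics; assembles class-balanced,
    subject-wise training sets; fits four supervised classifier families
    (penalised multinomial logistic regression, support vector machines,
    random forests and stochastic gradient boosting); and evaluates them
    with a leave-two-subjects-out protocol and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
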