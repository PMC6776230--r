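Package: plaqueomics
Title: Radiomic Texture Analysis and Machine Learning for Coronary Plaque CT Cross Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiomics pipeline for identifying advanced
    coronary atherosclerotic lesions from segmented CT angiography cross
    sections. Provides a 1919-feature radiomics engine (44 first-order
    statistics, gray-level co-occurrence and run-length texture matrices on
    six equal-width/equal-probability discretizations, and surface/fractal
    geometry parameters), NRRD image and mask I/O, histogram baselines (low
    attenuation area below 30 HU, mean attenuation), a randomized-search
    model-building procedure over eight classifier families with five-fold
    cross-validated AUC, DeLong confidence intervals and paired ROC
    comparison, and a synthetic plaque phantom generator so the whole
    analysis is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    glmnet,
    kernlab,
    nnet,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
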