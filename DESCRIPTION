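Package: pupilflow
Title: Predicting Pupil Diameter from Eye-Tracking Event Sequences and
    Extracting Cognition-Linked Residuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling near-future pupil diameter from classified
    eye-tracking event streams (fixations, saccades, blinks) recorded while
    viewing instructional video. Streams are segmented into fixed-length
    blocks whose first seconds provide input features and whose remainder
    yields an averaged fixation pupil-diameter label. A menu of predictors is
    provided, from a naive input-mean baseline and penalized linear models
    through tree ensembles to a bidirectional recurrent network (LSTM or GRU)
    with learned area-of-interest embeddings, trained with Adam and early
    stopping. The evaluation layer implements repeated-split RMSE, performance
    group comparisons via the Mann-Whitney U test, per-subject residual
    aggregation, Spearman and Fisher-Z correlation analyses, and tertile ROC
    AUC with a label-permutation null, so that the prediction residual can be
    assessed as a luminance-attenuated, cognition-linked pupillometric signal.
    A synthetic-study generator with known luminance-driven and arousal-driven
    pupil components supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
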