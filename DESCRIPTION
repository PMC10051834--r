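Package: sugarstep
Title: Free-Sugar Annotation of Food Composition Tables and Dietary Intake Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates food composition tables with free-sugar content using a
    four-step cascade: zero total sugar, zero-free-sugar food groups,
    100%-of-total-sugar food groups, and a stacked ensemble regression
    (support vector regression, random forest, gradient boosting, rule-fit)
    over seven nutrients for the remaining foods. Includes cross-dataset
    validation metrics (Pearson r, mean absolute error, menu-level daily-gram
    error), survey-weighted 24-hour-recall intake statistics (weighted
    mean/SE, Kruskal-Wallis with Dunn post hoc and Benjamini-Hochberg
    correction, weighted linear trend models, sugar-sweetened-beverage
    servings), and a synthetic-data generator producing mixture-based food
    tables with ground-truth free sugar and weighted recall surveys with
    planted wealth gradients.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    e1071,
    ranger,
    xgboost,
    glmnet,
    rpart,
    pracma,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
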