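Package: injurisk
Title: Injury Risk Prediction from Training-Load Time Series via Image
    Encoding and Deep Representation Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting next-day sports-injury risk from daily
    training-load logs. Sliding 7-day multivariate load windows are encoded
    as images (Gramian angular summation/difference fields, Markov transition
    fields, recurrence plots), rebalanced by a three-step resampling
    procedure (per-athlete balanced sampling, controlled unbalanced
    subsampling, Tomek-link cleaning plus SMOTE), compressed by a deep
    convolutional auto-encoder, classified by a focal-loss deep network, and
    explained by Shapley-value attribution. Includes a synthetic training-log
    generator with a plantable load-spike risk signal, a repeated hold-out
    evaluation protocol with Welch ANOVA and Games-Howell comparisons, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
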