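Package: it2fnn
Title: Interval Type-2 Fuzzy Neural Networks for Multiclass Tabular Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and inference for interval type-2 fuzzy neural networks
    (T2-FNN) with Takagi-Sugeno-Kang rule consequents, aimed at three-class
    tabular screening problems such as cardiotocography-based fetal health
    assessment. Provides Gaussian membership functions with uncertain means,
    closed-form type reduction, analytic-gradient stochastic training with
    momentum and a bold-driver learning rate under K-fold cross-validation,
    min-max scaling, a class-conditional linear-interpolation imputer for
    missing cells, confusion-matrix metrics, moment-calibrated synthetic data
    generators, and CSV/JSON interchange with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
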