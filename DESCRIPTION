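Package: drsarules
Title: Dominance-Based Rough Set Rule Induction for Tableting Process Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pharmaceutical formulation data with the
    dominance-based rough set approach (DRSA). Provides ordinal decision
    tables with nominal binarization and the gain/cost two-copy
    transformation, the f2 dissolution-profile similarity factor and its
    class discretization, dominance cones and lower/upper approximations of
    class unions, induction of minimal monotonic decision rules scored by
    support, strength, confidence and Bayesian confirmation measures,
    variable-consistency bagging of rule ensembles with voting
    classification, repeated stratified cross-validation, confirmation-based
    attribute relevance, and a synthetic formulation-table generator with
    planted monotone rules for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
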