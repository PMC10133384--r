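Package: favshift
Title: Favorability-Based Species Distribution Models and Fuzzy Range-Shift Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for presence/background species distribution modelling with
    the favorability function, a prevalence-independent transform of logistic
    presence probability. Cleans and grids occurrence records, selects
    bioclimatic predictors by correlation pruning, false-discovery-rate
    screening, stepwise AIC and significance trimming, fits binomial GLMs,
    evaluates discrimination (AUC, TSS, kappa) and calibration (Miller test),
    and compares favorability surfaces across time periods and climate
    scenarios with fuzzy-logic overlap indices (Schoener's D, Warren's I,
    fuzzy Jaccard and Baroni-Urbani & Buser) and fuzzy range-change maps.
    Includes a virtual-species simulator for end-to-end validation against a
    known environment-occurrence response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'favshift-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'grid.R'
    'raster-io.R'
    'occurrences.R'
    'selection.R'
    'favorability.R'
    'evaluation.R'
    'fuzzy.R'
    'projection.R'
    'synthetic.R'
    'pipeline.R'
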