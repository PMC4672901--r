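Package: mbmeta
Title: Meta-Analysis and Meta-Regression of Drosophila Mushroom-Body
    Short-Term Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation-statistics toolkit for synthesizing published
    T-maze olfactory short-term memory experiments in Drosophila.
    Computes delta-method percentage-change effect sizes from per-arm
    Performance Index summaries, pools them with DerSimonian-Laird
    random-effects meta-analysis (with driver/genotype subgroups and
    I-squared heterogeneity), and fits hierarchical precision-weighted
    meta-regression models with study clustering and shared-control
    block compound-symmetry covariance.  Includes driver cell-count
    regression and per-cell lobe potency models, a curated table of
    included experiments, a synthetic-data generator for parameter
    recovery studies, and a command-line reporting interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
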