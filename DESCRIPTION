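Package: spheroclear
Title: Substrate-Depletion Kinetics and Intrinsic Clearance from Fish Liver Spheroid Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-based substrate-depletion assays with
    primary hepatocyte spheroids from fish. Simulates or ingests tidy well-level
    parent-compound concentration time courses, fits first-order (two-parameter
    exponential decay) depletion kinetics per fish, classifies compounds showing
    no substrate depletion, scales depletion rate constants to in vitro and
    hepatic intrinsic clearance for in vitro-in vivo extrapolation (IVIVE),
    summarises inter-individual variability with one-way ANOVA and Tukey HSD
    compact letter displays, and scores human-to-fish metabolic read-across
    concordance from CYP-based metabolism profiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
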