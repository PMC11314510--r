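Package: mossrisk
Title: Trait-Based Extinction-Risk Modeling and Triage for Mosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to model the extinction risk of moss species from
    functional traits. Provides a species-by-trait data container with
    IUCN status binarization, absence imputation for binary traits and
    z-scaling of continuous traits; univariate trait screening with
    binary logistic models; construction of two maximal models and
    reduction to minimum adequate models by forward stepwise AIC
    selection; ROC-based classification cutoffs chosen with the Index
    of Union criterion under a sensitivity-priority override; and
    triage of Data Deficient species into threatened, possibly
    threatened and non-threatened verdicts by combining two risk
    models. A synthetic-cohort generator with known parameters supports
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
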