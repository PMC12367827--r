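Package: mixtriage
Title: Prioritisation of Plant-Protection Products and Dose-Addition
    Mixture Modelling from In Silico and In Vitro Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based triage pipeline for formulated plant-protection
    products (PPPs) and their co-formulants. Aggregates statistical and
    expert-system organ-toxicity predictions into a two-source score,
    applies formulation-content thresholds, pairs in silico CYP/P-gp
    inhibitor co-formulants with substrate active substances, and ranks
    co-formulants by sales-weighted tonnage. Also fits exponential, Hill
    and four-parameter logistic dose-response models with AIC selection,
    builds theoretical mixture curves under concentration (dose) addition
    with a parallel-curve construction, derives EC50/IC50 values, and
    classifies synergy or antagonism through the model deviation ratio.
    A seeded synthetic-data generator produces ground-truth-labelled
    formulation landscapes, prediction tables and dose-response data so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
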