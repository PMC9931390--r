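Package: gemscreen
Title: Pooled-Screen, Dose-Response and Fluctuation Analysis of Evolved
    Bacterial Gemcitabine Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mapping bacterial resistance to the
    nucleoside-analog chemotherapy gemcitabine and its consequences for
    drug availability. Covers barcode counting and negative-binomial Wald
    enrichment for pooled knockout screens, four-parameter logistic
    dose-response fitting with absolute IC50 inference, growth-curve AUC
    statistics for drug-breakdown classification, bivariate polynomial
    fitness-landscape fitting with EC50-front extraction for
    spheroid/bacteria co-cultures, Luria-Delbruck fluctuation analysis
    with partial plating (exact probability mass function, maximum
    likelihood, profile-likelihood intervals), and mutation annotation
    with a conservation-bias rank test. Includes seeded synthetic-data
    generators emulating each experimental design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
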