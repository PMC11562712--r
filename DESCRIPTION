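Package: riverkin
Title: Biodegradation Rate Constants of Micropollutants in River Water-Sediment Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Evaluation chain for modified OECD 309 river biodegradation
    incubations, from raw peak-area time series to first-order dissipation
    rate constants and their spatial analysis. Fits pooled log-linear
    kinetics with limit-of-quantification censoring, detects biphasic
    dissipation with a Chow structural-break test, corrects observed rate
    constants for sorption (dissolved fraction) and ionization speciation
    (normalization to a reference pH via the Henderson-Hasselbalch neutral
    fraction), gap-fills invalid estimates with a confidence-interval
    decision chain, summarizes spatial variability (standard deviation of
    log rate constants, fold differences, per-compound ANOVA), and
    attributes variability to environmental factors by redundancy analysis
    with permutation tests. Includes a synthetic-experiment generator that
    emulates the study design so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
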