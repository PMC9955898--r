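Package: fpromethee
Title: Fuzzy PROMETHEE II Outranking Analysis for Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-criteria decision analysis with the fuzzy PROMETHEE II
    outranking method. Alternatives scored on weighted max/min criteria --
    either as linguistic terms on a triangular-fuzzy scale or as raw numeric
    values -- are defuzzified with the Yager centroid index, compared
    pairwise through the classical PROMETHEE preference-function catalogue
    (Gaussian by default), and ranked by net outranking flow with tie-aware
    competition ranks. Includes one-at-a-time criterion-weight sensitivity
    analysis with rank-stability intervals, a seeded synthetic
    decision-matrix generator, bundled fixtures from a published evaluation
    of nine machine-learning brain-tumor classifiers, a plain-text CSV
    dialect for decision matrices, and tidy()/glance()/autoplot() methods
    for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
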