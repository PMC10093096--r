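Package: ihcbayes
Title: Bayesian Ranking of Lymphoid-Neoplasm Differentials from
    Immunohistochemistry Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Diagnostic decision support for hematolymphoid pathology.
    Maps a case's observed immunohistochemistry (IHC) panel onto a
    knowledge base of graded, disease-specific marker-expression
    frequencies and returns a ranked top-k differential diagnosis by
    naive-Bayes posterior probability. Includes the accompanying
    validation harness (case-exclusion filters, strict and inclusive
    hit definitions, per-entity error tables, chi-square dataset
    comparison), a curated demo knowledge base of lymphoma entities,
    and a seeded synthetic knowledge-base and cohort simulator for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
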