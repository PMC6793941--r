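Package: ipvdyad
Title: Couple-Level Classification of Intimate Partner Violence from
    Two-Informant Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores dyadic Family Maltreatment survey records into
    clinically significant versus low-impact intimate partner violence
    (IPV) under ICD-11-style criteria, classifies couples into a
    six-category mutually exclusive taxonomy using a two-informant union
    rule, and summarises direction, severity, repetition, intradyadic
    concordance and worst-case missingness bounds with small-cell
    disclosure masking. Includes a seeded synthetic dyad generator with
    known latent truth (category and direction mixtures, ordinal act
    frequencies, per-reporter under-reporting, missingness) so the whole
    pipeline is testable without access to sensitive survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
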