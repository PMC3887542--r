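Package: matepref
Title: Mating Preference Functions, Choosiness, and Attractiveness from
    Factorial No-Choice Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetics of mate choice with isogenic
    lines and no-choice mating assays. Simulates open-ended and unimodal
    preference functions and the factorial trial tables they generate
    (right-censored courtship and copulation latencies), computes line-level
    preference components (responsiveness, choosiness under several
    definitions, global attractiveness), and runs the inference chain used
    for such designs: type-III linear models on log latencies, Cox
    proportional-hazards models for censored copulation latency, Levene's
    test for genetic variation in choosiness, Benjamini-Hochberg FDR
    control, line-level genetic-correlation regression, and a permutation
    test of Kendall's coefficient of concordance that discriminates
    preference-function classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
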