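Package: chemocomp
Title: Carbon Budgets and Competition Metrics for Chemostat Ciliate Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chemostat competition experiments between
    ciliate consumers and microalgal prey: allometric biovolume-to-carbon
    conversion, Frost-Heinbokel grazing and clearance estimation with
    Michaelis-Menten functional-response fitting, censored population growth
    and filtration-rate statistics, a microbial-loop carbon-budget model of
    bacterial production fuelled by algal exudation, a seeded nitrogen-limited
    chemostat community simulator for end-to-end testing, and in-silico PCR
    utilities for rDNA internal transcribed spacer (ITS) clone markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
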