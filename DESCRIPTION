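Package: patchties
Title: Long-Term Social Ties from Colonial Breeding-Patch Resightings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and test long-term social ties between
    individually marked animals that breed in ephemeral patches within
    colonies. Builds period-level dyadic sociomatrices (together / apart /
    missing) and half-weight association indices from resighting records,
    tests persistence of co-breeding across periods with contingency tables
    and a Bayesian symmetric probit network regression (social relations
    model with additive individual effects and MCMC imputation of missing
    dyads), and referees both against a patch-size-preserving within-year
    permutation null. Includes a seeded colony simulator with latent social
    groups, annual patch turnover, perturbation regimes and imperfect
    detection, so every stage is testable with known ground truth.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
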