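Package: phenotherm
Title: Temperature-Dependent Phenology Models and Life-Table Simulation for
    Insect Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building temperature-driven phenology models for
    insects from constant-temperature life-history experiments, and for
    turning them into population-level predictions.  Fits linear degree-day
    models, the Logan development-rate function, logistic-product mortality
    and fecundity curves, Ratkowsky senescence models and shared-slope
    development-time distributions; simulates stochastic cohorts to obtain
    life-table growth parameters (intrinsic rate of increase, net and gross
    reproductive rates, generation and doubling times); and maps
    establishment and generation indices from monthly climate grids.
    Includes a synthetic-data generator emulating parasitoid
    life-table experiments so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
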