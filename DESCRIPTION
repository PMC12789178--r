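Package: nestclock
Title: Female Chronotype from Nest-Temperature Loggers and Its Fitness Consequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to extract daily activity onsets of incubating female birds
    from nest-temperature logger traces, convert them into conspecific-
    standardised onsets and per-female chronotypes, estimate within- and
    across-year repeatability from variance components, and fit a suite of
    fitness and life-history selection models with marginality-respecting
    backward elimination. Includes a seeded synthetic-data generator that
    emulates logger exports and breeding records with known ground truth, so
    the whole pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
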