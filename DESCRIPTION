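Package: playpref
Title: Play-Partner Preference Analysis for Group-Housed Juvenile Rats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for dyadic play-fighting event logs from
    group-housed juvenile rats: directed attack-count matrices, a
    partner-preference index with chance/strong/avoidance thresholds, a
    permutation (Mantel-style) screen against the equal-play expectation,
    play-symmetry and popularity metrics, day-to-day preference stability,
    weighted social networks with modularity and eigenvector centrality,
    repeated-measures ANOVAs, binary mixed-effects logistic models of
    preference predictors, a partner-availability correction with exact
    sign tests, and a synthetic-study generator with planted preference,
    tactic, and symmetry structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
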