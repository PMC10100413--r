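Package: planklag
Title: Lead-Lag Analysis of Plankton Functional Diversity and Lake
    Ecosystem State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether planktonic functional diversity
    leads, lags, or moves in synchrony with lake ecosystem state.
    Computes abundance-based state metrics (community PCA scores, total
    density, Fisher information, a multivariate variability index, and
    the zooplankton:phytoplankton ratio) and trait-based functional
    diversity series (functional richness, dispersion, and evenness from
    fuzzy-coded Gower dissimilarities) from monthly plankton density
    panels, then relates the two families of series by lagged
    cross-correlation against red-noise (AR(1)) surrogate nulls and by
    lagged convergent cross mapping with paired-lag causality-direction
    classification.  Includes seeded generators for lake-like community
    panels, trait tables, and coupled dynamical systems with known causal
    structure so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml,
    zoo
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
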