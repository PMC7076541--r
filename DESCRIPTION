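Package: diallelr
Title: Half-Diallel Combining-Ability Analysis, Heterosis, Variance
    Components, GGE Biplots and Distance-Matrix Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete analysis of half-diallel mating designs
    evaluated in randomized complete blocks across one or more environments.
    Implements Griffing's combining-ability estimation (methods 2 and 4) with
    standard errors and rankings, single-environment and combined analyses of
    variance with the GCA/SCA partition, expected-mean-squares variance
    components with narrow- and broad-sense heritabilities, mid-parent and
    best-parent heterosis with direction-aware better-parent rules, GGE biplot
    analysis of entry-by-tester diallel tables (average-tester-coordinate
    projections and the which-won-where polygon view), and phenotypic distance
    matrices (Euclidean, Mahalanobis) with seeded Mantel permutation tests.
    A synthetic-trial generator with known additive, non-additive,
    genotype-by-environment and error variance structure supports
    parameter-recovery verification of every estimator. User-facing functions
    take data frames and return tibbles; fitted objects carry broom-style
    tidy() and glance() methods and ggplot2 autoplot() displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
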