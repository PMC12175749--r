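Package: restodiv
Title: Multi-Scale, Multi-Metric, Multi-Facet Diversity Analysis for
    Restoration Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Incidence-based Hill-number rarefaction and extrapolation
    (orders q = 0 and q = 2) for taxonomic, phylogenetic (mean-PD) and
    functional (tau-threshold) diversity of plot/subplot survey data;
    phylogeny-informed iterative random-forest trait imputation using
    Abouheif proximities and Moran eigenvectors; Whittaker multiplicative
    beta decomposition at defined alpha and gamma scales; and
    invasion-timing by nutrient effect sizes with bootstrap confidence
    intervals. Includes a synthetic factorial-experiment generator
    (occupancy-based incidence, Yule trees, Brownian-motion traits with
    missingness) so that the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
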