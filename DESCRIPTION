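Package: endemap
Title: Spatial Phylogenetics of Endemism Centers and Their Projected Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based spatial phylogenetics for island endemic floras.
    Computes phylogenetic diversity and endemism surfaces with their
    comparison-tree counterparts (RPD, RPE), classifies centers of neo-,
    paleo-, mixed and super-endemism against a fixed-marginal randomization
    null (CANAPE), maps current-to-future change surfaces for species
    richness, phylogenetic structure, ecological generalism and phylogenetic
    beta-diversity turnover, derives bioregionalizations by unsupervised
    clustering with silhouette-based model choice and compares them with the
    V-measure, and relates endemism surfaces to environmental drivers through
    spatial autoregressive error models with AICc-based neighbor and
    predictor selection. A seeded synthetic-landscape generator (phylogeny,
    gridded ranges for current and future climate, covariates, traits and
    masks) makes the whole pipeline testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
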