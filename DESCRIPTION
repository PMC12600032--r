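Package: ecodelin
Title: Forest Ecosystem Delineation from Inventory Plots, Species Turnover
    and Object-Oriented Random-Forest Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for national-scale delineation of
    forest ecosystems from tree inventory plots. Computes the Importance
    Value Index (IVI) to select dominant canopy species, builds the
    balanced-variation (turnover) component of the Bray-Curtis
    dissimilarity between plots, clusters sites with order-randomised
    UPGMA selected by cophenetic correlation, chooses the number of
    bioregions with an elbow rule on the between-cluster dissimilarity
    ratio, and resolves single-site clusters by Simpson similarity.
    Characterises clusters with species test values, contributive species
    sets and a row-stochastic cluster-interaction matrix projected onto
    environmental gradients. Extends clusters to the landscape with an
    object-oriented random-forest classifier on segment quantile features
    (recursive feature elimination, collinearity pruning, stratified
    cross-validation, permutation importance with p-values, partial
    dependence), and compares old-growth versus secondary forest
    composition between plot clusters and predicted ecosystems. Includes a
    synthetic inventory/landscape generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
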