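Package: paleoniche
Title: Deep-Time Ecological Niche Modelling and Taphonomic Bias Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying habitat suitability of fossil clades and the
    preservational biases that filter their record. Implements a presence-background
    maximum-entropy ecological niche model with subsample AUC evaluation, jackknife
    and permutation variable importance, TSS thresholding and multi-threshold habitat
    area quantification on outcrop versus continental masks; a virtual-taphofacies
    model built from BQART sediment flux over DEM-derived drainage basins and surface
    runoff, classified by Jenks natural breaks; kernel-density and Getis-Ord Gi*
    hotspot analysis with 2x2 contingency tests (Pearson chi-squared with and without
    Yates' correction, Fisher's exact test); and a seeded synthetic palaeo-world
    generator (DEM, epicontinental seaway, monthly climate, outcrop masks, virtual
    species, preservation-biased sampling) so the full pipeline is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
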