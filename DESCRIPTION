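Package: swampcat
Title: Presence-Background Niche Modelling and Habitat Accounting for a
    Lowland Wetland Felid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for presence-only species distribution
    analysis of the flat-headed cat and similar lowland wetland specialists:
    a maximum-entropy presence/background niche model with replicate
    ensembles, AUC evaluation and permutation variable contributions;
    omission-threshold range maps; land-cover and human-population-density
    reclassification into ordinal habitat classes; circular buffer-zone
    habitat tallies around occurrence records; log-likelihood G tests of the
    historical-versus-recent habitat contrast with spatial-autocorrelation
    corrections; a weighted geometric-mean habitat suitability index; and
    habitat-loss and protected-area accounting. Ships a seeded synthetic
    landscape generator so the full pipeline runs without external raster
    downloads.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
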