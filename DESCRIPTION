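Package: phylosoil
Title: Phylogenetic Signal in Local-Scale Plant-Soil Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies evolutionary signal in species-soil associations on
    mapped forest plots. Overlays a stem census on gridded soil and topographic
    layers to build per-species median soil "traits", derives composite soil
    fertility axes by principal component analysis, and tests for
    phylogeny-wide signal (mean standardized independent contrasts and
    Blomberg's K) and node-specific signal (tip-average and ancestral-average
    node means against tip-shuffle permutation nulls) on a user-supplied
    phylogeny. Includes a synthetic-data generator producing pure-birth trees,
    Brownian species optima, spatially autocorrelated soil landscapes, and
    clustered habitat-filtered stem placement, so the whole pipeline can be
    exercised and calibrated without access to restricted census data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
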