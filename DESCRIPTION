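Package: occomm
Title: Multi-Season Multi-Species Occupancy Models for Camera-Trap
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating mammal community richness and dynamics
    from camera-trap surveys. Builds occasion-binned detection tensors from
    raw detection and deployment tables, fits data-augmented multi-species
    multi-season (dynamic) occupancy models and single-species dynamic
    occupancy models with a bespoke Metropolis-within-Gibbs sampler
    (forward-filtering backward-sampling for latent occupancy chains),
    derives posterior species richness, colonization and persistence rates,
    and summarises community functional composition by trophic guild and
    body-mass class. Includes a survey simulator drawing from the exact
    generative model so every stage can be validated by parameter recovery
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
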