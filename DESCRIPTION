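Package: oddwave
Title: Oddball ERP Design, Simulation, and Cluster-Based Permutation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for auditory oddball event-related potential (ERP) studies
    of the mismatch-negativity (MMN) family: constrained pseudo-random oddball
    sequence generation, an idealized 10-20 spherical montage with a spatial
    adjacency graph, a component-summation forward simulator of multichannel
    epochs, threshold-based artifact rejection with per-trial channel
    interpolation, identity difference-wave algebra for swapped-role designs,
    spatiotemporal cluster-based sign-flip permutation tests, and
    fractional-latency and amplitude point measures with 2x2 within-subject
    inference. Developed around a Mandarin tone-sandhi oddball design with
    disyllabic stimuli, but the machinery is generic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
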