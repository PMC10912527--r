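Package: pollennet
Title: Heterospecific Pollen Deposition and Plant-Pollinator Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conspecific and heterospecific pollen (CP/HP)
    deposition on stigmas in a plant community alongside the structure of its
    bipartite plant-pollinator network. Computes network- and species-level
    specialization indices (H2', d'), species strength, closeness centrality
    and Chao1 sampling completeness from scratch; summarises per-stigma pollen
    loads into per-species and community statistics; classifies each species'
    CP-HP accrual pattern (linear, exponential, or none) by competing
    regressions; runs cross-species trait and network-metric regressions with
    standardized coefficients and one-way ANOVAs across pattern groups; and
    generates seeded synthetic communities (visitation networks and stigma
    pollen loads) with known ground truth for end-to-end testing.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
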