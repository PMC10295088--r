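Package: fluxpin
Title: Constrained Flux Sampling and Informative-Flux Extraction for
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting metabolic flux distributions by uniform
    sampling of the steady-state flux polytope of a constraint-based
    metabolic model, and for extracting the exchange fluxes that are most
    informative for pinning down the metabolic state of a cell. Includes a
    flux balance analysis / flux variability analysis engine with a built-in
    bounded-variable simplex solver, an artificially-centred hit-and-run
    sampler with parallel-chain (OptGP-style) orchestration and thinning,
    nested-FBA generation of (substrate, growth, product) constraint seeds
    with sequential constrained sampling, multidimensional-scaling
    comparison of sample diversity, hit-count flux-importance ranking,
    correlation-based flux grouping, minimum-flux-number estimation, and
    validation of sampled distributions against 13C metabolic flux analysis
    reference tables. Reads and writes COBRA JSON and SBML Level 3 (fbc)
    models and ships toy-model generators with known solution-space
    geometry for testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
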