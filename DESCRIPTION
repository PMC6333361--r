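Package: trophicweb
Title: Mass-Balance Food Webs, Mixed Trophic Impact and Benthic-Pelagic
    Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, balance and interrogate Ecopath-style mass-balance food-web
    models. Solves the steady-state master equations for per-group biomass or
    ecotrophic efficiency, derives the consumption flow matrix, respiration and
    detritus budgets, computes fractional trophic levels, omnivory indices and
    system-level flow statistics, performs Mixed Trophic Impact analysis with
    fishing fleets as components, and quantifies fisheries exploitation and
    benthic-pelagic coupling through cross-domain flux and impact
    decompositions. Includes a generator of balanced-by-construction synthetic
    food webs for validation, and a fixture reproducing the structure of a
    Mediterranean shelf-slope ecosystem model with 72 functional groups and 18
    fleet segments.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
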