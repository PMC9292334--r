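Package: mnrecycle
Title: Micronutrient Recycling by Zooplankton: Box Model and Driver Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A zero-dimensional mixed-layer plankton ecosystem model of trace-metal
    (Fe, Zn, Cu, Co, Mn) recycling by microzooplankton, with Droop-type variable
    phytoplankton quotas, fixed zooplankton stoichiometry, and food-quality
    dependent assimilation. Provides preindustrial-control and climate-forcing
    scenario pairs, a fixed-food-quality counterfactual experiment, and a
    variance-attribution pipeline (ordinary least squares plus the LMG
    relative-importance decomposition) that partitions recycling-flux and
    recycling-stoichiometry variance among food quality, prey quantity, sea
    surface temperature and zooplankton biomass, with ternary dominance
    classification. Includes a synthetic driver-panel generator with analytic
    population importance shares for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
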