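Package: c4dehyd
Title: Bundle-Sheath Conductance and C4 Flux Inference from Concurrent
    Gas-Exchange and Isotope Measurements During Fast Dehydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers C4 photosynthetic fluxes (Rubisco carboxylation and
    oxygenation, PEPC carboxylation), bundle-sheath CO2 and O2
    concentrations and leakiness from concurrent leaf gas-exchange,
    chlorophyll-fluorescence, CO2-isotopologue and water-isotopologue
    measurements taken during fast dehydration of C4 leaves (maize,
    sorghum). Solves the five-equation C4 biochemical system in closed
    form, computes observed and modelled 13C discrimination and the 18O
    chain yielding mesophyll CO2 concentration, and fits a linear
    dependence of bundle-sheath conductance on leaf water potential
    (g_BS = g_BS0 + k * Psi_L) per replicate with a seeded differential
    evolution optimizer. Includes Monte-Carlo error propagation,
    mixed-model elasticity analysis, and a forward simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
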