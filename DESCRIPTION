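Package: osteosim
Title: Microsimulation Cost-Effectiveness Model of Sequential
    Teriparatide/Alendronate in High-Risk Osteoporotic Women
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level (microsimulation) Markov cost-effectiveness
    model comparing two years of daily teriparatide followed by ten years of
    weekly alendronate against alendronate alone, in community-dwelling
    osteoporotic women with prior vertebral fracture. Implements the drug
    pricing model for generic/biosimilar scenarios (unit price to annual
    cost, brand/generic blending, discount-by-market-share grids), real-world
    persistence and adherence scaling of trial efficacy with linear offset
    (washout) effects, annual-cycle simulation of fracture events and
    mortality with individual-level trackers, discounted cost and QALY
    accounting from societal and health-care-sector perspectives, incremental
    cost-effectiveness ratios, one-way deterministic sensitivity analysis,
    price-threshold analysis, and two-level probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Inputs the source
    study drew from a prior technical appendix (age-specific fracture
    incidence, baseline utilities, disutility multipliers, life table) are
    replaced by clearly-labelled synthetic generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
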