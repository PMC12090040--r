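Package: dendrotraits
Title: Tree-Ring Growth, Wood Anatomy and Isotope-Derived Water-Use
    Efficiency Under Drought and Rising CO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-proxy analysis of long-term conifer decline from
    tree-ring data. Derives basal area increments and drought resilience
    indices from ring widths, quantitative wood-anatomical traits (Mork
    earlywood/latewood partition, cell-wall thickness, lumen area,
    theoretical hydraulic conductivity, implosion-safety ratio,
    standardized tracheidograms) from per-cell tables, and intrinsic
    water-use efficiency from tree-ring carbon isotope ratios via the
    discrimination chain. Computes the Standardised
    Precipitation-Evapotranspiration Index (SPEI) from monthly climate
    with Thornthwaite potential evapotranspiration, classifies extreme
    years, and fits smooth-response (GAM) models of water-use efficiency
    against atmospheric CO2 and August SPEI12 with health-status and
    period interactions, including first-derivative slope curves and
    percent-change summaries. A seeded synthetic-data generator with
    known ground truth emulates a three-species Mediterranean
    decline-and-mortality study design so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    emmeans,
    jsonlite,
    lme4,
    mgcv,
    sandwich,
    stats,
    tools,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
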