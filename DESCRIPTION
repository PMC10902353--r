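Package: livestockCH4
Title: City-Level Livestock Methane Emission Inventory with Dynamic
    Emission Factors
Version: 0.1.0
Authors@R:
    person("Inventory", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Bottom-up construction of city-level livestock methane
    inventories from activity panels (stock and slaughtered head counts)
    and spatially and temporally dynamic emission factors. Implements
    IPCC Tier 2 enteric fermentation emission factors from a net-energy
    gross-energy-intake model, a milk-production regression for dairy
    cattle, Tier 1 lookups for minor species, manure-management emission
    factors from volatile-solids excretion with climate-dependent methane
    conversion factors, average-lifespan weighting of stock and
    slaughtered populations, hierarchical city/province/national
    aggregation, gap-filling of missing activity records from meat
    production, Monte Carlo uncertainty propagation, and a synthetic
    activity-panel generator for testing the full pipeline without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
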