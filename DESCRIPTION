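Package: doputil
Title: Dissolved Organic Phosphorus Utilization Analysis for
    Nutrient-Addition Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for coastal microcosm bioassays probing how
    nitrogen-rich aerosol and riverine additions drive dissolved organic
    phosphorus (DOP) utilization. Implements the bioassay response
    statistic Delta-R, Redfield-stoichiometry nutrient drawdown budgets
    and the potential maximum DOP utilization (Delta-DOP*), difference-
    method DOP error propagation, endmember dosing arithmetic, one-way
    ANOVA with Tukey HSD compact letters, segmented regression estimation
    of the DIP threshold for alkaline phosphatase activity, limitation and
    phosphorus-source classification, and the global Log10(Chl a / DIP)
    index on 1-degree grids, together with a mechanistic microcosm
    simulator and synthetic global-field generator so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    ncdf4,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    jsonlite,
    segmented,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
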