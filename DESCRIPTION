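Package: deerflux
Title: Nutrient Import and Export Budgets for Wild Deer Grazing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Accounting of annual nitrogen and phosphorus fluxes mediated by
    wild red deer (Cervus elaphus) grazing in protected semi-natural open
    habitats. Converts raw dung-survey records (faecal accumulation rate
    counts with a decay-experiment correction), pellet-group dry masses,
    plant and faecal nutrient concentrations and cage-based forage-removal
    estimates into per-period nutrient import (faecal plus modelled urinary
    nitrogen) and export (grazing offtake), aggregates them to habitat-level
    annual budgets with Gaussian error propagation and 95% confidence
    intervals, and compares net balances against atmospheric deposition
    scenarios. Includes a synthetic survey generator with analytically known
    true budgets so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
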