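Package: soltol
Title: Solvent Tolerance Assays in Sealed Anaerobic Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for solvent tolerance assays of anaerobic
    bacteria grown in sealed vials with volatile chlorinated solvents.
    Converts solvent doses into dissolved aqueous concentrations via a
    closed-system Henry's-law mass balance, extracts specific growth rates
    from OD600 time series, estimates EC50 values by linear interpolation
    with extrapolation and censoring rules, and computes cross-solvent
    tolerance analytics (percent of aqueous solubility, free-phase
    tolerance classification, normalized tolerance scores, and regressions
    of EC50 against solvent-free growth rate and log Pow). Includes a
    synthetic assay simulator with known ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
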