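Package: oxyplan
Title: Quantification of National Medical Oxygen Needs, Equipment Gaps and
    Hypoxaemia-Management Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a facility-based model of national medical oxygen
    demand: per-patient gaseous-oxygen volumes from clinical assumptions
    (hypoxaemia prevalence, flow rate, therapy duration by ward), expected
    hypoxaemic caseloads from bed counts and annual bed turnover, and
    hierarchical roll-ups from ward to facility, facility type, region and
    country.  Adds an equipment gap analysis with cylinder-equivalent volume
    conversion, a DHIS-2-style set of hypoxaemia-management and oxygen-use
    indicators computed from monthly facility reports with stock-ledger
    validation, and a synthetic facility-data generator so the full pipeline
    runs without access to confidential health-facility assessment data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
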