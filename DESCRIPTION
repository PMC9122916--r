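Package: aoaflux
Title: Quantification of Archaea-Driven Lake Nitrification from Single Cells to
    Ecosystem Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify ammonia oxidation by planktonic
    ammonia-oxidizing archaea (AOA) in stratified lakes. Estimates potential
    ammonia oxidation rates from 15N-tracer incubation time series by linear
    regression with a one-tailed significance filter, converts nanoSIMS
    single-cell isotope measurements into 15N atom fractions, potential growth
    and ammonium assimilation rates, derives per-cell carbon content from cell
    geometry through an allometric volume-to-carbon relation, and integrates
    qPCR abundance time series over time and lake volume into annual
    ecosystem-level nitrogen fluxes with propagated uncertainties. Includes a
    synthetic-data generator emulating seasonal abundance dynamics, tracer
    kinetics and single-cell enrichment mixtures so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
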