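Package: cufate
Title: Copper Fate in Lakes: Settling Removal Times and a Two-Box
    Water-Sediment Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the fate of copper added to lentic surface
    waters. Implements the closed-form settling-removal framework linking
    first-order water-column loss rates to lake depth, particle flux and the
    solid-water distribution coefficient; a two-compartment (completely
    mixed water column over a single active sediment layer) kinetic-
    equilibrium mass-balance simulator with simplified copper speciation
    (empirical or concentration-dependent distribution coefficients, Cu-DOC
    complexation, acid-volatile-sulfide precipitation, oxic-phase sorption);
    a first-order removal-time estimation pipeline for observed
    concentration time series with confidence-interval propagation and an
    interpolation fallback; and seeded synthetic-data generators for spike,
    repeated-dose and flow-through experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
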