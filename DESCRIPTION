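Package: co2scd
Title: Summer CO2 Drawdown from High-Latitude Atmospheric CO2 Records
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes long atmospheric CO2 concentration records
    (daily in-situ or weekly flask-style) into a quadratic trend, four
    seasonal harmonics and digitally filtered residual components, and
    derives the summer CO2 drawdown (SCD) -- the decline in detrended CO2
    between early July and late August -- as a proxy for the net summer
    carbon uptake of the upwind land region. Provides zero-crossing and
    trough phenology dates, cosine-latitude and footprint-weighted
    regional aggregation of gridded climate and vegetation fields,
    extreme-warm-day indices, and the statistical machinery for
    detrended partial correlations with controls, subsample resampling
    distributions, regression sensitivities, period comparisons, moving
    windows, lagged correlations and pixelwise correlation maps. A
    synthetic-data generator with a known coupling between drawdown and
    regional summer temperature makes the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ncdf4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
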