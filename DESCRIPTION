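Package: planthydro
Title: Genotype-Specific Plant Hydraulics and Drought Acclimation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Tools for linking xylem hydraulic traits of cotton genotypes to
    whole-plant drought behaviour. Fits Weibull xylem vulnerability curves and
    summary statistics (P50), converts soil texture to Brooks-Corey hydraulic
    properties via pedotransfer regressions, interpolates field soil texture by
    ordinary block kriging, and runs a half-hourly soil-plant hydraulic
    continuum simulation (Sperry-style supply-demand with rhizosphere, root and
    shoot elements) over a growing season. Derived stress metrics (whole-plant
    conductance loss, hydraulic safety margins, relative safety margin, midday
    transpiration divergence) support in-silico genotype-by-environment
    experiments under staged drought scenarios. Includes seed-deterministic
    synthetic generators for every input class (vulnerability-curve
    measurements, spatially correlated soil texture fields, diurnal
    meteorological forcing with irrigation pulses, noisy layered soil-moisture
    observations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
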