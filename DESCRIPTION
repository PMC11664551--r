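Package: navelopt
Title: Environmental Drivers of Navel Orange Fruit Quality and Optimal-Range
    Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline linking orchard environmental factors
    (meteorological, topographic, soil) to navel orange fruit-quality traits.
    Provides descriptive statistics with variability classification, Pearson
    correlation screening with two-level significance marks, single-response
    partial least squares regression (NIPALS) with VIP-based variable
    selection, ordinary least squares refits producing per-trait regression
    equations with F tests, and linear programming over the fitted equation
    system to derive optimal environmental-factor ranges. Ships a packaged
    equation system and factor bounds for the Gannan navel orange core
    production area, and a seeded synthetic-orchard generator (Gaussian
    copula over truncated-normal marginals) for testing the full chain
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    boot,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
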