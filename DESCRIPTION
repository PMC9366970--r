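Package: parkactivation
Title: Neighborhood Activation Measures and Park-Use Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures of neighborhood commercial activity around urban parks
    built from establishment-level hourly popularity profiles: land-use
    density, commercial activity diversity (number of broad establishment
    types), and the L2 norm of the daily neighborhood activation
    distribution, computed within metric buffers around park target areas.
    Includes nearest same-type popularity imputation for exhaustive
    establishment listings, Poisson generalized estimating equations with
    parks as clusters for direct-observation (SOPARC-style) scan counts,
    a three-model battery with a mediation-attenuation report, and a
    seeded synthetic-data generator for the full study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    geosphere,
    optparse
Config/testthat/edition: 3
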