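Package: frostdendro
Title: Reconstruction of Spring-Frost Growth Reductions from Tree-Ring Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria reconstruction of spring-frost-induced growth
    reductions in deciduous tree-ring networks. Builds residual site and
    regional chronologies (negative-exponential plus 50-year spline
    detrending, autoregressive prewhitening, Tukey biweight robust mean,
    EPS/rbar/mean-sensitivity quality statistics), derives per-year frost
    indices from daily station temperatures (standardized spring window
    minima, a warm-spell/cold-snap frost-risk index, day-of-year frost
    pinpointing), screens monthly growth-climate correlations, and
    integrates five eliminatory criteria plus two additional criteria into
    a four-level confidence scale for reconstructed frost events. Includes
    readers and writers for Tucson/decadal ring-width files and climate
    CSV, and a seeded synthetic generator of tree-ring networks and daily
    climate with injectable frost and drought events for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
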