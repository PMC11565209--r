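Package: gasx
Title: Gas-Exchange Trait Extraction for Stomatal Kinetics and Anatomy Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to extract photosynthetic and stomatal traits from
    infrared gas-analyser logs across accession panels: steady-state
    light-response (A/Q) fitting by a rectangular hyperbola with apparent
    quantum yield as a model parameter; induction kinetics of net
    assimilation and stomatal conductance after a step increase in
    irradiance, fitted with a sigmoidal time-constant model; anatomical
    maximum stomatal conductance from stomatal density and pore geometry;
    intrinsic water-use-efficiency steady states; and panel-level
    statistics (ANOVA, Tukey HSD with compact letter displays, Pearson
    correlations). A synthetic-data generator emulates the measurement
    protocols so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
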