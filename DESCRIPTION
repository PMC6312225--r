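Package: carlites
Title: Ecological Status of Rocky Shores with the CARLIT Index
Version: 0.1.0
Authors@R:
    person("carlites", "authors", email = "methods@example.org", role = c("aut", "cre"))
Description: Assessment of the ecological status of Mediterranean rocky-shore
    water bodies from cartographies of littoral macroalgal communities
    (CARLIT). Provides the community sensitivity catalogue with the
    co-dominance averaging rule, length-weighted Ecological Quality Ratios
    (EQR) against geomorphology-specific reference values, Water Framework
    Directive status classification, the Land Uses Simplified Index (LUSI)
    for coastal anthropogenic pressure, and restricted maximum likelihood
    (REML) partitioning of EQR variance across water bodies, years and
    surveyors.  Includes seeded generators of synthetic survey cartographies
    and EQR panels so every stage of the pipeline can be tested without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
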