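Package: b12flux
Title: Flux Balance Analysis and Strain-Design Screens for Vitamin B12
    Production in Pseudomonas putida
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models aimed
    at cobalamin (vitamin B12) overproduction in Pseudomonas putida KT2440.
    Provides a metabolic model container with SBML Level 3 FBC v2 and
    BIGG-style JSON readers and writers, a bounded-variable simplex solver for
    flux balance analysis, medium application via exchange-reaction uptake
    bounds, reaction knockin bundles for pathway curation, exhaustive
    multi-deletion screening over EC-annotated candidate reactions, a
    dimensional-analysis benchmark against fermentation yields, and a
    generator of small mass-balanced toy networks with analytically known
    optima for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
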