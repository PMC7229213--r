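Package: netgs
Title: Network-Based Genomic Selection for Metabolic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts plant growth by combining constraint-based metabolic
    modelling with genomic prediction. Steady-state fluxes are estimated for
    each genotype from a stoichiometric model carrying a genotype-specific
    biomass reaction, per-reaction marker-effect models (rrBLUP) are trained
    on the estimated fluxes, and predicted flux breeding values are projected
    back onto the steady-state flux polytope to obtain a breeding value for
    growth. Includes reference flux estimation by flux balance analysis with
    carboxylation:oxygenation and starch:sucrose ratio constraints, a
    parsimonious-FBA variant, flux variability analysis, transfer of
    predictions to unseen environments via reference-genotype exchange-flux
    ratios, robustness resampling of the reference flux distribution,
    cross-validation orchestration with diagnostic checks, and generators for
    synthetic stoichiometric networks and accession panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    quadprog,
    jsonlite,
    xml2,
    yaml,
    vegan,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
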