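Package: gemcurate
Title: Curation Toolkit for Genome-Scale Metabolic Models of Marine
    Heterotrophs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating a genome-scale metabolic model of a marine
    heterotrophic bacterium grown at seawater osmolarity: salt-corrected cell
    dry weight estimation from pellet weighings, growth-rate-dependent biomass
    composition built from genome-derived monomer profiles, estimation of
    growth- and non-growth-associated maintenance energy from batch-culture
    time series coupled to flux balance analysis, parsimonious gap-filling
    against growth phenotypes, and growth-rate-dependent flux balance analysis
    by fixed-point iteration. Includes a synthetic-data module (a toy metabolic
    network with known energetics, simulated batch cultures, composition
    measurements, pellet weighings and plate curves) so the whole pipeline is
    exercisable and testable without external data, plus SBML (Level 3 with
    flux-balance constraints) input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
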