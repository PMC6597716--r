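Package: thermokin
Title: Kinetic and Thermodynamic Analysis of Temperature Adaptation in Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how enzymes trade thermal stability against
    low-temperature catalytic activity. Fits Michaelis-Menten kinetics by
    nonlinear least squares, converts kcat and Km into transition-state-theory
    energy profiles along the reaction coordinate (Eyring, Arrhenius and
    van't Hoff analyses), fits two-state thermal unfolding curves to estimate
    melting midpoints, selects candidate mutation sites on a ligand-bound
    structure by comparing a thermophile/mesophile sequence pair within a
    distance shell of the bound ligands, and quantifies the
    stability-activity trade-off by regression. A forward-model generator
    produces synthetic kinetic datasets, melt curves and toy structures for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
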