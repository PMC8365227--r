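Package: aneuflow
Title: Desk-Scale Hemodynamics of Stented Sidewall Aneurysms
Version: 0.1.0
Authors@R:
    person("aneuflow", "developers", email = "aneuflow@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the metal coverage rate (MCR) of an
    intracranial stent or flow diverter, modified by device choice,
    overlapping and compaction, changes intra-aneurysmal hemodynamics in an
    idealized sidewall aneurysm. Provides parametric virtual stent patterns
    (laser-cut and braided lattices) with exact raster MCR computation, a 2D
    incompressible pulsatile Navier-Stokes solver on a staggered grid with a
    Womersley inlet and a solidity-dependent porous-screen closure at the
    aneurysm neck, hemodynamic summary metrics (energy loss, average neck
    velocity, inflow rate and their reduction rates versus the unstented
    control), a study pipeline with Pearson correlation of MCR against each
    metric, and analytic validation fixtures (Poiseuille, oscillatory
    Womersley channel flow, Taylor-Green decay).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
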