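Package: vwfmarg
Title: Mesoscopic Simulation of von Willebrand Factor Margination in Blood Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional dissipative particle dynamics (DPD) simulation of
    blood flow in a slit channel, with red blood cells modelled as closed
    bead-spring rings and von Willebrand factor (VWF) as a self-attracting
    bead-spring polymer. Provides the full analysis stack for near-wall
    polymer dynamics: centre-of-mass distributions, RBC-free-layer thickness,
    margination probability, regional chain extension, bead adhesion activity,
    the potential-adhesion probability, and assembly of hematocrit/shear-rate
    diagrams, together with Poiseuille-flow validation utilities, a
    deterministic fixture generator for the observables, extended-XYZ
    trajectory I/O and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
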