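Package: micellab
Title: Quantitative Analysis of Chaperone Protein Micelle Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the self-assembly of chaperone proteins
    into equilibrium micelles from single-particle and hydrodynamic
    measurements. Implements calibration and weighting of mass-photometry
    particle-mass distributions, Svedberg-equation fusion of mass and
    sedimentation-coefficient distributions into size, packing-density and
    water-fraction profiles, single-exponential dissociation kinetics with
    Arrhenius activation-energy extraction, and solution-chemistry
    calculators (protein net charge versus pH, buffer speciation and ionic
    strength, Debye length, refractive-index increments). A synthetic-data
    generator emulates the statistical structure of the measurements so
    that every stage of the analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
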