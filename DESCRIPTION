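Package: skmflux
Title: Spiegler-Kedem Modelling of Nanofiltration Permeate Flux
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling pressure-driven membrane filtration of
    polyphenol-rich streams with the Spiegler-Kedem irreversible-thermodynamics
    transport model. Implements Arrhenius-type temperature dependence of the
    hydraulic permeability, van 't Hoff osmotic pressure with film-theory
    concentration polarization, an implicit permeate-flux solver, bounded
    nonlinear least-squares estimation of membrane parameters with linearized
    confidence intervals and an NRMSE-based goodness-of-fit statistic, a
    synthetic-data generator for parameter-recovery studies, and bundled
    nanofiltration flux datasets for a polypiperazine membrane processing
    red-wine lees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
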