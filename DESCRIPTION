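Package: crevsim
Title: Crevice-Corrosion Modelling for Conical Implant Taper Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional crevice-corrosion simulator for the convergent
    gap formed at conical trunnion/bore junctions of modular hip implants.
    Builds a roughness-aware gap profile from the cone mismatch angle and a
    periodic machined surface trace, discretizes the electrolyte resistance of
    the annular gap, computes the ohmic (IR) potential drop driven by the
    passive current of the alloy, and classifies each depth as passive,
    actively corroding, or negligible against the alloy's passivation and
    corrosion potentials. Includes named presets for FeCr, Ti6Al4V and CoCrMo
    alloys, sensitivity sweeps over mismatch angle and roughness scale,
    Tafel-extrapolation and Faraday's-law helpers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
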