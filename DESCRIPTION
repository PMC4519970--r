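Package: lumifret
Title: Foerster Theory and Time-Gated Luminescence Analysis for Lanthanide
    FRET Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing lanthanide-based FRET biosensors that pair a
    long-lived Tb(3+) donor with a fluorescent-protein acceptor. Implements the
    Foerster-theory core (overlap integral, Foerster radius, per-distance
    transfer rate, efficiency and quenched lifetime) over conformational
    distance ensembles; time-gated detection of multi-exponential luminescence
    decays; reabsorption (inner-filter) correction and photobleach-subtraction
    spectral processing; hyperbolic saturation-binding fits with bootstrap
    uncertainties; and seeded synthetic-data generators (polymer-chain distance
    sampling, line and band spectra, titrations, decays) so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
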