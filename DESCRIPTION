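Package: prekin
Title: Binding and Exchange Kinetics from Paramagnetic Relaxation
    Enhancement NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for paramagnetic metallohost-guest systems
    studied by paramagnetic relaxation enhancement (PRE) NMR. Fits
    inversion-recovery and CPMG relaxation decays, decomposes observed
    relaxation rates into diamagnetic, inner-sphere and outer-sphere
    contributions, runs exchange-regime diagnostics, fits solvent-reporter
    binding titrations to a 1:1 isotherm, converts inner-sphere rates into
    guest residence times and dissociation rate constants (with
    reaction-order correction), and extracts activation parameters by
    Eyring analysis, including threading rate constants for rotaxane-type
    systems. Ships a two-site-exchange synthetic data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
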