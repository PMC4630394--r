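Package: woodChemIR
Title: FT-IR Chemometric Calibration and Loading-Integrity Diagnostics
    for Wood Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calibrates wood chemical composition (extractives, lignin,
    cellulose, hemicellulose) from mid-infrared absorbance spectra using
    principal components regression and NIPALS partial least squares,
    with wavenumber-window selection and Savitzky-Golay first-derivative
    pretreatment.  Extracts peaks from model loading and coefficient
    profiles, matches them to literature infrared band assignments, and
    tests the location residuals for variance and mean differences
    between modelling algorithms.  Ships a composition-weighted
    synthetic-spectrum generator with known band structure so the whole
    workflow can be validated end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
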