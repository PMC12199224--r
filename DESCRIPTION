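Package: aqc13c
Title: Isotope Calibration of Atom Percent 13C for AQC-Derivatized Amino
    Compounds Measured by High-Resolution Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes atom percent 13C enrichment of amino acids and amino
    sugars from isotopologue peak intensities of their
    6-aminoquinolyl-N-hydroxysuccinimidyl carbamate (AQC) derivatives,
    corrects the signal-size-dependent underestimation caused by detection
    loss of higher isotopologues, fits per-compound isotope calibration
    curves (linear over the full enrichment range, second-order polynomial
    at low enrichment), and predicts calibration curves for compounds that
    lack isotopically labeled standards from the fold dilution of carbon
    introduced by derivatization, via a four-stage regression cascade.
    Includes a mechanistic isotopologue simulator (binomial isotope
    incorporation, reagent carbons at natural abundance, intensity
    censoring, multiplicative noise), model-evaluation statistics (R2,
    MAD, MAPD, 1:1-line regression) and LOD/LOQ estimation for both
    concentration and isotope enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
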