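Package: silutil
Title: Silicic-Acid Utilization from Diatom Silicon Isotopes with
    Constrained Stratigraphic Zonation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers photic-zone silicic-acid utilization from diatom
    silicon-isotope (d30Si) records under an open-system steady-state
    fractionation model (with a closed-system Rayleigh baseline),
    bounds the influence of cryophilic sea-ice diatoms with a
    two-end-member mass balance, identifies stratigraphic zones by
    constrained incremental sum-of-squares (CONISS) clustering with
    broken-stick significance testing, aligns covariate proxy records
    onto the isotope sample ages with an age-gap exclusion rule, and
    screens/ordinates the aligned variables (DCA gradient length, then
    scaled PCA). Includes a synthetic multiproxy record generator with
    regime-shift mean structure and AR(1) noise for end-to-end testing
    and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
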