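Package: ocumag
Title: Ocular Magnification Correction for OCTA Fundus Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates ocular axial length from keratometry and spherical
    equivalent with a multiple linear regression, and corrects transverse
    magnification error in fundus measurements derived from optical
    coherence tomography angiography (OCTA) - foveal avascular zone area
    and linear dimensions - using the Littmann-Bennett formula. Includes
    the full method-comparison toolkit used to evaluate estimated against
    measured axial length: Bland-Altman limits of agreement with
    confidence intervals, intraclass correlation of absolute agreement,
    paired t-tests, coefficient-of-repeatability exceedance and relative
    change, plus a seeded synthetic biometry-cohort simulator and a
    command-line interface for batch workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
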