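Package: smallfieldr
Title: Small-Field Radiosurgery Dosimetry Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dosimetric analysis chain for ultra-small circular photon beams
    (3-25 mm radiosurgery cones). Implements a radially symmetric convolution
    beam model with virtual fluence sources derived by van-Cittert iterative
    deconvolution, beam-scan analytics (FWHM, 20-80% penumbra, percentage
    depth dose), a radiochromic film dosimetry pipeline (red-channel net
    optical density, cubic calibration, median filtering, film output
    factors), the detector perturbation-factor calculus for small-field
    output corrections (housing, sensitive-volume material and
    volume-averaging components), and a parametric output-factor field-size
    fit. A synthetic-data generator emulates water-phantom scans, film scans
    and detector readings with known ground truth so the whole chain is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tiff, jsonlite, minpack.lm
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
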