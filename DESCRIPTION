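Package: gazefuse
Title: Gaze-Dependent Flood-Illumination Adaptive Optics Image Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers overlapping en-face retinal images acquired with a
    flood-illumination adaptive optics (FIAO) ophthalmoscope at shifted gaze
    positions and fuses them with per-pixel statistics that highlight
    gaze-varying structures, chiefly drusen. Registration uses FFT phase
    correlation for translation and a Fourier-Mellin log-polar step for
    rotation, combined over all image pairs by a quality-weighted global
    solve. Fusion statistics (standard deviation, variance, covariance and
    the maximum pairwise standard deviation) operate on defined pixels only,
    so partially covered canvas regions are handled honestly. The package
    also ships a synthetic retinal phantom generator with known ground-truth
    transforms and lesion tables, quantification utilities for drusen
    diameters, size classes, annulus ratios and grader variability, and the
    directional-imaging standard-deviation z-projection variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
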