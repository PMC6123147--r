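Package: portaltrack
Title: Enhancement and Markerless Tumor Tracking for Megavoltage Portal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how image enhancement affects markerless
    tumor tracking on megavoltage electronic portal imaging device (EPID)
    images. Implements the forward degradation model (Lorentzian point
    spread function blur plus additive noise), three enhancement operators
    (total-variation regularized deconvolution, contrast-limited adaptive
    histogram equalization, and 3x3 median denoising), three portal image
    quality metrics (contrast, signal-to-noise ratio, and an edge blurriness
    measure based on the 10-90% width of a Boltzmann sigmoid fit), a
    mask-based tumor tracker minimizing the mean of summed squared pixel
    differences (MSSD) over an integer search window with a multiple-minima
    detection-failure rule, and an end-to-end four-arm comparison pipeline
    exercised on synthetic bar-pattern phantoms and moving-tumor cine
    sequences with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    minpack.lm,
    jsonlite,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'portaltrack-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'GrayImage-methods.R'
    'synthetic.R'
    'enhance.R'
    'metrics.R'
    'tracking.R'
    'experiment.R'
    'io.R'
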