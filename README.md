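# portaltrack

Image enhancement versus markerless tumor tracking on megavoltage portal
images — a tested, reproducible comparison pipeline.

Megavoltage (MV) images from an electronic portal imaging device (EPID)
are acquired with the treatment beam itself, which makes them the ground
truth for where the beam goes — and notoriously hard to read: low
contrast, blurred, noisy. When the EPID runs in cine mode for markerless
tumor tracking, two questions arise: which enhancement makes the frames
readable for visual verification, and does enhancing the frames help or
harm the automatic tracker? `portaltrack` provides the full apparatus to
study both on synthetic scenes with known ground truth.

## What is implemented

* **Forward model** `g = Hf + η`: Lorentzian point-spread blur
  `h(x,y) ∝ (1 + (x² + y²)/λ²)^(−3/2)` (default λ = 0.5 mm) plus additive
  Gaussian noise, with mirror-boundary convolution and bit-reproducible
  seeding (`lorentzianPSF`, `degradeImage`).
* **Synthetic scenes**: a bar-pattern quality phantom with annotated
  white/black reference squares and a tilted edge (`makeQC3Phantom`), and
  moving-tumor cine sequences over structured background
  (`makeCineSequence`).
* **Three enhancement arms**: total-variation deconvolution minimizing
  `μ‖Hf − g‖² + Σ√(βx²(Dxf)² + βy²(Dyf)²)` with a guaranteed
  non-increasing objective trace (`tvDeconvolve`); contrast-limited
  adaptive histogram equalization with 8 × 8 subsections
  (`claheEnhance`); and 3 × 3 median denoising (`medianDenoise`).
* **Quality metrics**: contrast `(Iw − Ib)/Iw`, SNR `Iw/σb`, and
  blurriness as the 10–90% width `2·dx·ln 9` of a Boltzmann sigmoid
  fitted to the tilted-edge profile (`contrastMetric`, `snrMetric`,
  `fitBoltzmann`, `blurrinessMetric`), normalized to the original arm.
* **Mask-based MSSD tracker**: binary mask from an ROI polygon,
  exhaustive integer search in a 10 × 10 px window, undetected frames via
  multiple score minima, accuracy `e(k) = d(k) − d(0)` in mm against
  feature-based origins `Tm(k)` (`buildMask`, `locateTumor`,
  `evaluateAccuracy`, `summarizeErrors`).
* **Four-arm pipeline**: `runPhantomExperiment`, `runTrackingExperiment`,
  `detectionRateStudy`, `writeReport`.

## Worked example

```r
library(portaltrack)

pe <- runPhantomExperiment()          # four-arm quality comparison
round(pe$table[, c("SNR", "Blurriness", "Contrast")], 2)
#>              SNR Blurriness Contrast
#> original   1.00       1.00     1.00
#> deblurred  0.54       0.38     1.01
#> clahe      0.09       0.55     7.52
#> denoised   2.31       1.97     0.99
```

Each row is one enhancement arm applied to the *same* degraded phantom,
each metric divided by the original arm's value. Reading the table:
deconvolution sharpens (blurriness 0.38) at the cost of noise
(SNR 0.54); contrast enhancement multiplies contrast 7.5-fold while
amplifying noise strongly (SNR 0.09); median denoising suppresses noise
(SNR 2.31) but blurs (1.97). Contrast is essentially untouched by the
other two arms.

```r
te <- runTrackingExperiment()         # 1 reference + 75 object frames
te$summaries[, c("arm", "meanSI", "meanLR", "nDetected", "nUndetected")]
#>         arm meanSI meanLR nDetected nUndetected
#>    original   0.25   0.13        75           0
#>   deblurred   0.34   0.24        75           0
#>       clahe   0.40   0.21        75           0
#>    denoised   0.23   0.13        75           0
```

Mean absolute superior–inferior and left–right tracking errors in mm
against the feature-based origins, plus detection counts. On this
well-conditioned scene every arm detects every frame; the detectability
differences only appear in the quantized low-contrast regime probed by
`detectionRateStudy()`, where the original arm drops frames to exact
score ties and the CLAHE arm keeps detecting.

## Package vignette

`vignettes/portaltrack-methods.Rmd` documents the models, the parameter
choices and their defaults, the numerical decisions (solver, fit
initialization, tie tolerance), what the synthetic scenes do and do not
emulate, and known limitations.
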