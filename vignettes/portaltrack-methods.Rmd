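---
title: "Enhancement and markerless tumor tracking for megavoltage portal images"
author: "portaltrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancement and markerless tumor tracking for megavoltage portal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portaltrack)
```

## The problem

Megavoltage (MV) images from an electronic portal imaging device (EPID) are
formed by the treatment beam itself, which makes them geometrically ideal
for verifying where the beam actually hits — but radiographically poor:
Compton-dominated interactions produce intrinsically low subject contrast,
detector and scatter blur smears edges, and quantum noise is high. During
markerless tumor tracking, where the EPID runs in cine mode and a tracker
localizes the tumor frame by frame, the question arises whether image
enhancement (a) helps a human verify the tracking at a glance and (b)
helps or harms the automatic tracker itself.

`portaltrack` implements the full comparison apparatus for that question:
a forward degradation model with known ground truth, three enhancement
operators, three image-quality metrics, a mask-based tracker, and a
four-arm experiment pipeline (original, deblurred, contrast-enhanced,
denoised). Everything runs on synthetic scenes, so every downstream claim
is checkable against ground truth.

## The observation model

The observed image is modeled as

$$ g = Hf + \eta $$

where $f$ is the ideal image, $H$ convolution with a point spread
function, and $\eta$ additive noise. The PSF is an isotropic Lorentzian,

$$ h(x, y) \propto \Big(1 + \frac{x^2 + y^2}{\lambda^2}\Big)^{-3/2}, $$

with width parameter $\lambda$ in mm; $\lambda = 0.5$ is a representative
value for a 6 MV beam on an amorphous-silicon panel. `lorentzianPSF()`
samples this at pixel centers and renormalizes to unit sum.

Two numerical points deserve emphasis:

* **Heavy tails.** The mass of $h$ outside radius $R$ is
  $\lambda / \sqrt{\lambda^2 + R^2}$ — it decays only like $1/R$. Any
  compact kernel support therefore truncates a visible fraction of the
  mass (about 16% at the default half-width of
  $\lceil 6\lambda/\Delta \rceil$ px for $\lambda = 0.5$ mm,
  $\Delta = 0.784$ mm). `lorentzianPSF()` warns whenever the truncated
  fraction exceeds 1%. The truncated tail corresponds to long-range glare;
  for edge-width and tracking purposes the renormalized compact kernel is
  the intended operator, so the pipeline accepts (and silences) this
  warning deliberately rather than carrying a 129-pixel-wide kernel.
* **Boundary handling.** `degradeImage()` convolves with mirror
  (symmetric) padding so that constant regions stay constant right up to
  the borders — dark frame edges would otherwise corrupt metric boxes
  placed near the image periphery.

The noise model is additive zero-mean Gaussian with configurable standard
deviation — the simplest model consistent with "noise added". Noise is the
only random element; for a fixed seed the entire scene generation is
bit-reproducible. An optional quantization step (`quantStep`) rounds
intensities to discrete levels after degradation, emulating detector
readout; exact score ties in the tracker (below) only arise on quantized
data.

## Synthetic scenes and what they do (not) emulate

`makeQC3Phantom()` builds a bar-pattern quality phantom: five vertical bar
groups at distinct spatial frequencies, a white and a black reference
square, and a large two-level region split by a near-vertical edge tilted
5°. The geometry is *inspired by* bar-pattern QC phantoms, not a replica;
all metric regions are returned as annotations, so no metric depends on
hard-coded coordinates. The surround is an *open-field* region at twice
the plate level — in an MV portal image the unattenuated beam is the
brightest thing in the field, and the attenuating phantom plate sits at
the bottom of the intensity range. This matters quantitatively for
contrast enhancement (below). Plate contrast defaults to ±2% around the
plate level: genuinely low-contrast, as MV imaging is.

`makeCineSequence()` emulates cine acquisition: a smooth-edged elliptical
blob (raised-cosine taper, default radius 12 px, 20% contrast decrement)
moves along an integer-pixel trajectory over a fixed background of
low-frequency illumination gradients plus rib-like bands; each frame is
degraded independently. The default trajectory is a quasi-periodic
breathing-like excursion within ±4 px — inside the tracker's ±5 px search
window — over 1 reference + 75 object frames at 512 × 384 px and
0.784 mm spacing.

What the generator does *not* emulate: anatomical background from CT/DRR,
deformable or out-of-plane motion, scatter gradients tied to patient
geometry, detector lag/ghosting, or Poisson (dose-dependent) noise
statistics. Passing tests therefore demonstrate correctness of the
*operators and the pipeline* under controlled conditions, not clinical
performance on patient images.

## The three enhancement arms

**TV deconvolution** (`tvDeconvolve`) approximately minimizes

$$ \mu \lVert Hf - g \rVert^2 + \sum_i \sqrt{\beta_x^2 (D_x f)_i^2 +
   \beta_y^2 (D_y f)_i^2} $$

with forward-difference gradients $D_x, D_y$. The weight $\mu$ sits on
the data-fidelity term (the standard convention for this formulation).
The solver is monotone gradient descent with backtracking line search on
an $\varepsilon$-smoothed TV term ($\varepsilon = 10^{-8}$, far below any
image contrast of interest), with $H$ applied as a periodic convolution
via the FFT. Monotone descent was chosen deliberately over faster
splitting schemes: the per-iteration objective trace is part of the
function's contract (it must never increase), which backtracking descent
guarantees by construction. Divergence (objective exceeding 10× its
initial value) raises an error; in exact arithmetic it cannot happen.

Defaults: $\beta_x = \beta_y = 1$ (isotropic TV), 200 iterations maximum,
relative-change stopping tolerance $10^{-5}$ (typically reached in ~20
iterations), $\mu = 1000$. The default $\mu$ was fixed by a coarse grid
search over $\mu \in \{30, 100, 300, 1000, 3000\}$ on the default phantom
scene: small $\mu$ lets the TV term flatten the weak plate contrast
(widths *grow*), while $\mu = 1000$ sharpens the tilted edge
(normalized width ≈ 0.38) at the cost of amplified noise (normalized
SNR ≈ 0.54) — exactly the qualitative trade a deconvolution arm should
show.

**CLAHE** (`claheEnhance`) wraps Zuiderveld's contrast-limited adaptive
histogram equalization (via EBImage) behind the package's interface:
8 × 8 subsections, 256 bins, clip limit expressed as a fraction of the
tile pixel count (default 0.01, converted to EBImage's mean-height
multiple as `clipLimit * nBins`). Intensities are min–max scaled to
[0, 1] first. The equalized result is rescaled by the input *maximum*
(zero-anchored) rather than mapped back onto the input [min, max]
interval: contrast $(I_w - I_b)/I_w$ and SNR $I_w/\sigma_b$ are intensity
*ratios*, and re-adding the original baseline offset would algebraically
cap the achievable contrast gain near 1 no matter how well the histogram
equalization separates the levels. With zero anchoring, arms remain on a
common scale (the maxima agree) while ratio metrics reflect what the
operator actually did. A constant image is returned unchanged, and the
output for any positive affine remap of the input is a pure scaling of
the original output (identical ranks).

**Median denoising** (`medianDenoise`) replaces each pixel by the median
of its 3 × 3 neighborhood (mirror padding), computed by a fixed
19-exchange compare–exchange network applied to whole shifted images, so
the filter is exact and fast without compiled code.

## Quality metrics

For annotated white/black boxes (each ≥ 10 × 10 px):

* contrast $= (I_w - I_b) / I_w$ with $I_w, I_b$ the box means;
* SNR $= I_w / \sigma_b$ with $\sigma_b$ the sample (n − 1) standard
  deviation inside the black box.

Both are invariant under multiplying all intensities by $c > 0$; contrast
is deliberately *not* offset-invariant — it is the formula, not an
idealized property, that is implemented.

**Blurriness** is the 10–90% width of a Boltzmann (logistic) sigmoid

$$ y = a_\mathrm{low} + \frac{a_\mathrm{high} - a_\mathrm{low}}
   {1 + e^{-(x - x_0)/dx}} $$

fitted to an intensity profile across the tilted edge. For this
parameterization the width has the closed form $2\,dx \ln 9$, which is
asserted for every returned fit. Profiles are sampled by bilinear
interpolation at 4× oversampling; positions are arc length in pixel
units, so oblique profiles have non-integer spacing. The fit is
Levenberg–Marquardt with data-driven initialization (asymptotes from the
5th/95th percentiles, $x_0$ from the midrange crossing, $dx$ from the
local slope) and up to five deterministic restarts with rescaled initial
$dx$; the logistic is evaluated through `plogis`, which is overflow-safe,
and falling edges are fitted on the reversed axis. The 10–90% levels are
defined on the *fitted asymptotes*, not the sample extremes, making the
width robust to isolated noise spikes. A profile that does not cross its
midrange exactly once (after light smoothing) is rejected as non-edge-like.
Known limitation, reproduced on purpose: an edge-width metric measured at
one edge says nothing about resolution loss elsewhere (e.g. fogged fine
bars after median filtering) — the bar groups exist in the phantom
precisely so this blind spot is visible to users.

`blurrinessMetric()` additionally averages 5 parallel profiles spaced
1 px apart perpendicular to the line — standard slanted-edge practice
that suppresses noise without biasing the width (the edge crossing shifts
by at most tan 5° ≈ 0.09 px per line).

All three metrics are reported raw and normalized to the original arm
(`normalizeReports`), whose normalized triple is exactly (1, 1, 1).
`profileMinMaxMatch()` affinely maps profiles to a common min/max for
fair visual comparison.

## The tracker

A region of interest drawn on the reference frame is rasterized to a
binary mask (pixel-center even-odd rule, `buildMask`); the
reference-frame intensities under the mask form the template. For each
object frame, `locateTumor` evaluates the mean of summed squared
differences (MSSD) at every integer offset within a square search window
(half-width 5 px → the customary 10 × 10 px region; motion is assumed
pre-verified to stay inside it, so the window stays centered on the
reference position with no motion prediction). The minimum offset is the
tracked position. If the global minimum is attained at more than one
offset — compared with relative tolerance $10^{-9}$, since no numeric
rule exists beyond "multiple minimum points" — the frame is *undetected*.
Search is integer-pixel only; no subpixel interpolation.

Accuracy is referenced to feature-based origins: per frame, the mean of
three feature points is the origin $T_m(k)$ (synthetically: three
jittered copies of the true center, jitter SD 0.3 px by default);
$d(k) = T_m(k) - T_t(k)$ in mm, and the reference-corrected error is
$e(k) = d(k) - d(0)$. Summaries report per-axis (rows =
superior–inferior, columns = left–right) mean and sample SD of $|e(k)|$
over detected non-reference frames — absolute components, recorded as a
fixed convention since "mean distance" is ambiguous between signed and
absolute — plus detection counts. Undetected frames are excluded from
the statistics. Conversion to mm happens at evaluation time, in one
place.

A structural property worth stating: applying the *same* strictly
increasing affine intensity map to reference and object frames multiplies
every MSSD score by the squared gain and therefore leaves every argmin —
and every detection decision — unchanged. This is the mechanism by which
matched contrast enhancement of both frames can preserve tracking
behavior even though the images look radically different.

## The four-arm experiment

`runPhantomExperiment()` degrades the pristine phantom once and applies
every arm to that same degraded image — enhancement is the *only*
difference between arms — then computes and normalizes the three metrics.
`runTrackingExperiment()` enhances every cine frame with the arm's
operator (reference frame included, so both images entering the MSSD are
processed identically), builds the mask on the enhanced reference,
tracks, evaluates, and summarizes. Quality metrics are not computed for
cine frames (they are a phantom-protocol concept). Arms whose reference
frame fails to track are reported as failed without stopping the others.
`writeReport()` writes the two summary tables as CSV, a JSON report with
full provenance, and a parameter log.

`detectionRateStudy()` probes the detectability question statistically:
50 seeded replicates of a small (96 × 96, 21-frame) quantized
low-contrast cine scene (`detectionStressScene`: blob contrast ≈ 1.5
8-bit steps, noise ≈ 0.3 step, 8-bit quantization) are tracked with the
original and CLAHE arms on identical frames. In this regime the original
arm's score surface ties exactly on some frames (undetected), while
CLAHE's local remapping spreads the quantized levels apart and typically
breaks the ties. The study reports per-replicate detection counts; the
result is statistical and scene-dependent and should be read as a
qualitative direction, not a universal claim.

## Problem sizes and reproducibility

Default study conditions: phantom and cine frames are 512 × 384 px at
0.784 mm spacing; 1 + 75 cine frames; tracker window ±5 px; the
detectability study uses 50 replicates of 20 object frames at 96 × 96 px.
The test suite exercises smaller scenes (96–128 px frames, 5–200 frames)
chosen so each property is tested at the smallest size where it is
meaningful; the tracker's noise-robustness property uses 200 frames at
10% noise-to-contrast. Every random element — noise fields, origin
jitter, replicate seeds — derives from explicit integer seeds, and
identical seeds give bit-identical scenes, reports, and files.

## Known limitations

* The Lorentzian PSF is borrowed from a different detector resolution
  than the emulated one; whether $\lambda$ should be rescaled with pixel
  size is not settled, so $\lambda$ and spacing are exposed as
  independent parameters and no rescaling is guessed.
* The TV solver favors a guaranteed-monotone trace over speed; on
  512 × 384 frames a full deconvolution takes a couple of seconds.
* The contrast ratio achievable by CLAHE on synthetic piecewise-constant
  scenes is sensitive to the clip limit and to how much histogram mass
  lies between the two reference levels; narrow-histogram scenes clip
  hard and amplify less than textured clinical images do.
* Tracking error magnitudes on synthetic scenes (sub-millimetre) are much
  smaller than on patient images, where feature-point selection on
  anatomy dominates the error budget; only directions and detection
  behavior transfer, not magnitudes.
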