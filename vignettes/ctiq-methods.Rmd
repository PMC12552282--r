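---
title: "Methods: reference-free CT image quality, dose accounting and rater agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free CT image quality, dose accounting and rater agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

`ctiq` quantifies the objective image quality of soft-tissue CT regions of
interest without a reference image, carries exam dose records through the
CTDIvol → DLP → effective-dose chain, and measures chance-corrected
agreement between raters of ordinal image-quality scores. This vignette
documents the estimators, their assumptions, the tunable parameters, and
the design decisions taken where the procedures admit more than one
reasonable realization.

## The noise model and its isolation

The pipeline assumes an ROI whose underlying anatomy is piecewise smooth —
one or two tissue plateaus, possibly separated by a blurred boundary —
corrupted by approximately stationary, approximately additive noise. The
signal is removed, not modeled: a Gaussian lowpass copy (width `lp_sigma`,
default 2 px) is subtracted from the image, leaving a highpass residual
dominated by noise. The lowpass is *mask-aware*: kernel weights are
renormalized over valid pixels, so the ROI border causes no edge
darkening and a constant image is reproduced exactly up to the border.

Subtracting a smoothed copy also removes part of the noise itself. For
white noise of standard deviation σ the residual has standard deviation
σ·a with the attenuation

```
a = sqrt(1 − 2·g0 + Σ g²)
```

computed from the discrete 2D kernel g (center weight g0);
`highpass_attenuation()` evaluates it, including the generalization to
noise pre-correlated with a Gaussian of known width. For the default
`lp_sigma = 2`, a ≈ 0.9697. This factor is exact for the kernel actually
used, which is why the tests can pin the residual's Monte-Carlo standard
deviation to σ·a within 3%.

The residual is converted to a noise map by a standard-deviation filter:
at every pixel whose full **circular window** (radius `window_radius`,
default 3 px) lies inside the mask, the sample standard deviation
(denominator n − 1) of the residual in the window. Circular windows keep
the statistic isotropic; pixels whose window leaves the mask are
undefined rather than silently computed from fewer samples.

## STDmin, SNR, CNR

The minimum-noise estimate `STDmin` is the mean of the five lowest
circle-averaged noise-map values over **densely sliding** circles of
diameter `region_diameter_px = 12` (every pixel whose circle fits in the
region is a candidate). Dense placement makes the estimator deterministic
and exhaustive; ties are resolved by (score, row, column) ordering, so
the "five lowest" always has a unique answer.

Taking the lowest order statistics of a noisy field biases the estimate
below the field's mean. On homogeneous noise the bias is a stable
multiplicative factor b, which depends on the filter settings and on the
candidate count (larger regions reach deeper into the minimum), not on σ.
It is measured once on white-noise phantoms in the validation-grid
geometry (two-tissue 256×256 step, half-plane regions, 10 seeds) and
shipped with the package (`order_stat_factor()`, b ≈ 0.817); the
recovery tests then predict `STDmin ≈ σ·a·b` and `CNR ≈ ΔSI/(σ·a·b)`.
The shipped value applies to the default settings; other settings trigger
an on-the-fly recalibration.

`SNR = SI/STDmin` and `CNR = ΔSI / mean(STDmin)` follow directly. A zero
noise estimate (possible only on synthetic noiseless input) raises an
error instead of returning infinity — an infinite SNR is never meaningful
downstream.

## Modal signal intensity

SI is defined from the grey-value histogram with a fixed bin width
(default 20 HU, interpreted as Hounsfield units). Two realization choices
matter:

* **SI is the mean of the pixel values inside the modal bin**, not the
  bin center — this removes the half-bin quantization bias while staying
  a histogram-derived quantity.
* **The modal bin is anchored by a maximal-count sliding window**: the
  width-20 interval is placed where it captures the most pixels (ties go
  to the window closest to the overall mean). With any *fixed* anchoring
  the modal bin can sit up to half a bin off the distribution mode, and
  the mean of a width-20 bin that is off-center on a Gaussian of σ = 20
  lands up to ~9 HU from the mode — an anchoring artifact, not an
  estimator property. The sliding placement centers the bin on the
  densest intensity range, making SI unbiased for symmetric noise at any
  offset. Fixed anchorings (`"min"`, `"origin"`) remain available via the
  `anchor` argument for comparison with other implementations.

The two-tissue split is histogram-based: most populated bin, most
populated bin at least two bins away, threshold at the valley bin center
between them (midpoint of the mode centers when the valley is tied). The
split is refused unless the valley is strictly below both modes, which is
what routes unimodal ROIs to the single-tissue path — for a unimodal
histogram every candidate "second mode" in the tail fails the
strict-valley test. At high noise the pixelwise thresholded masks are
salt-and-pepper (individual pixels cross the threshold), so per-tissue
measurements run on a spatially coherent partition: the Gaussian-smoothed
(σ = 2 px) tissue indicator thresholded at 0.5. This keeps the
12-px-circle candidate set non-empty up to σ = 40 on a 100 HU contrast.

## Entropy and edge sharpness

Grey-value entropy is the Shannon entropy (base 2) of the normalized
bin-width-20 histogram over the tissue mask, bins anchored at the in-mask
minimum; empty bins contribute zero. It is checked against closed-form
cases (0, 1, and 1.75 bits).

Sharpness is reported as the 10–90% transition distance of an
error-function edge model — the standard edge-spread-function convention;
the quantity is an *interpretation*, since "sharpness of the transition"
admits several definitions. Implementation: boundary pixels are located
on the interface of the smoothed-indicator partition, normals come from
the indicator gradient, intensity profiles are sampled by bilinear
interpolation (half-pixel steps, ±8 px), aligned at their 50% crossing,
pooled, and fitted with `A + (B−A)·Φ((t−μ)/s)` by profiled least squares
(the amplitude enters linearly; μ and log s by Nelder–Mead). The width is
`2·Φ⁻¹(0.9)·s ≈ 2.563·s`, in pixel-spacing units. On noiseless phantoms
with Gaussian boundary blur σ_b ∈ {1, 2} px the recovered width is within
10% of 2.563·σ_b; an ideal step measures ≤ 1.2 px (sampling-limited). At
least 8 boundary pixels and a few usable profiles are required, otherwise
the measurement errors out.

## The phantom generator

`generate_phantom()` emulates exactly the statistical structure the
estimators assume: one or two constant plateaus (vertical step or
centered disk), a Gaussian-blurred boundary (`edge_blur_sigma`), and
additive Gaussian noise that is white or Gaussian-correlated
(`noise_corr_sigma`). The noise field is **rescaled after correlation
filtering** so its realized sample standard deviation equals
`noise_sigma` exactly — ground truth is sharp, and recovery tests need no
allowance for generator variance. Intensities stay floating point by
default; a `quantize` switch rounds to integers to mimic HU images.
Tissue truth masks exclude the blurred boundary band (template further
than 1% of the contrast from both plateaus), so per-tissue truth is
unambiguous under blur.

The default validation grid (`default_phantom_grid()`) crosses
σ ∈ {0, 5, 10, 20, 40} HU with correlation ∈ {0, 1.5} px and blur
∈ {0, 1, 2} px — 30 phantoms of 256×256 px at plateaus 50/150 HU, fixed
seeds. These conditions bracket realistic soft-tissue CT contrasts
(ΔSI = 100 HU) and noise levels from strongly denoised (σ = 5) to very
noisy (σ = 40) reconstructions; differing denoising strengths are
represented *only* as noise/blur levels. What the phantoms deliberately
do not emulate: anatomical texture, reconstruction streaks or other
non-stationary artifacts, non-Gaussian noise, and the spatially varying
correlation of iterative or learned reconstructions. Passing recovery
tests therefore demonstrates estimator correctness under the stated
model, not performance on arbitrary clinical images.

Phantom sizes were chosen so the whole grid generates and evaluates in
well under a minute on one core: 256×256 gives each half-plane region
roughly 28k STDmin candidate circles, enough for the order statistics to
stabilize, while the 20-seed stability checks use 128×128.

## Dose accounting

The chain is pure arithmetic and is kept exact: kV selection is the
inclusive step rule (80 kV ≤ 70 kg < 100 kV ≤ 80 kg < 120 kV),
`DLP = CTDIvol × L` with L defaulting to the fixed 25 cm comparison
length, and `E = k·DLP` with `k = 0.0058` mSv/(mGy·cm) for head/neck.
k is a user parameter, not a physics model; no organ-dose simulation is
attempted. Summaries report mean ± SD per protocol; effective dose is
rounded to 2 decimals and percent reductions to 1 decimal in reports,
with full precision retained internally. Records whose stored kV
contradicts the weight rule are flagged, not corrected.

## Gwet's AC₂

For items i with r_i raters and K ordered categories with weights w, the
estimator is AC₂ = (Pa − Pe)/(1 − Pe) with

* Pa: per item, the weighted agreement over all ordered rater pairs,
  Σ_k r_ik (r*_ik − 1) / (r_i (r_i − 1)) with r*_ik = Σ_l w_kl r_il,
  averaged over items with r_i ≥ 2;
* Pe = T_w/(K(K−1)) · Σ_k π_k(1 − π_k), with T_w the total weight and
  π_k the mean of r_ik/r_i over all items.

Default weights are linear ordinal, `w_kl = 1 − |k−l|/(K−1)`; quadratic
and identity weights are available (identity reduces AC₂ to AC₁). The
variance follows Gwet's item-level linearization and the 95% interval is
the normal approximation truncated to [−1, 1] — a documented
interpretation, as is pairwise deletion of missing cells within items. A
table in which every rater uses a single category throughout is perfect
agreement by convention, flagged degenerate. The implementation is tested
to 12 decimals against an independent transcription of the same estimator
built from explicit rater-pair loops.

## Numerical conventions and degenerate inputs

* Masks are inclusive; circle membership is center distance ≤ radius;
  matrix indices are 1-based (row, column), pixel centers at integers.
* Histogram bins are half-open `[lo, lo + w)` with the top value included
  in the last bin for fixed anchorings.
* Empty masks, non-positive widths, ROIs smaller than one filter window,
  and candidate sets smaller than `k_lowest` raise errors naming the
  offending quantity rather than degrading silently.
* Offsetting an image by an exact multiple of the bin width shifts SI by
  that constant and leaves STDmin, ΔSI, CNR, entropy and sharpness
  unchanged (tested as an invariant).
* All simulation-based tests fix their seeds; estimator stochasticity is
  assessed across ≥ 20 seeds where a stability claim is made.

## Known limitations

* Strictly 2D; no volumetric noise estimation.
* The noise model is stationary additive Gaussian; heavy streaking or
  photon-starvation artifacts violate the assumptions of both STDmin and
  the histogram split.
* STDmin's calibration factor b is geometry-dependent (candidate count);
  quantitative SNR/CNR predictions should reuse the region geometry the
  factor was measured on, or recalibrate.
* Correlated noise is attenuated differently by the highpass step and
  under-registered by small-window statistics; STDmin remains linear in σ
  (tested) but its absolute scale differs from the white-noise
  prediction, so cross-algorithm comparisons should compare like with
  like.
* Image input is limited to portable headerless CSV/whitespace arrays
  (plus JSON ROI specs); clinical formats must be converted upstream.
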