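---
title: "Quantifying choriocapillaris flow deficits: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfd)
```

## The problem

The choriocapillaris (CC) is the single fenestrated capillary layer of the
inner choroid, roughly 10–30 µm thick, directly below Bruch's membrane (BM).
On en-face OCT angiography its perfusion is quantified through *flow
deficits* (FDs): contiguous regions of the binarized flow image classified as
lacking detectable flow. Four read-outs are standard: the FD percentage of
the quantified area (FD%), the number of contiguous FD components, their mean
area in µm², and their total area in mm².

Every step of the measurement — which axial slab is projected, which device
and acquisition mode produced the scan, how shadow artifacts are compensated,
and how the image is binarized — changes the numbers. `ccfd` implements the
full processing chain as tested functions so these sensitivities can be
studied on synthetic scenes whose ground truth is known exactly.

## The processing chain

Given a registered pair of structural and flow en-face images normalized to
$[0,1]$:

1. **Compensation.** The structural slab is inverted ($1-S$), smoothed with a
   Gaussian of physical scale $\sigma$ (default 15 µm), and multiplied into
   the flow image. Where drusen or RPE changes attenuate the signal, the
   inverted structural image is bright, so shadowed flow signal is boosted
   and attenuation-induced false FDs are suppressed. With `output_rescale`
   (default) the product is affinely stretched to span $[0,1]$.
2. **Binarization.** Phansalkar local adaptive thresholding over a circular
   window of radius $R$ pixels (default 4):
   $$t = \mu\left(1 + p\,e^{-q\mu} + k\left(\frac{\sigma_w}{r} - 1\right)\right)$$
   with $(k, r, p, q) = (0.25, 0.5, 2, 10)$, where $\mu$ and $\sigma_w$ are
   the window mean and population SD. A pixel is FD iff its value is $\le t$.
   The $p\,e^{-q\mu}$ term boosts the relative threshold in dark regions,
   which is what makes the method suitable for low-contrast CC slabs — and
   also what turns deeply shadowed regions into false FDs when compensation
   is skipped.
3. **Quantification.** Connected components of the FD mask (8-connectivity by
   default, 4 by flag) are measured with physical scaling by the pixel pitch:
   FD% over all image pixels, component count, mean component area (µm²),
   total area (mm²). These satisfy the exact identities
   $\mathrm{count}\times\mathrm{mean\ size\ (µm^2)} = \mathrm{total\ (mm^2)}\times 10^6$
   and, with no size filter,
   $\mathrm{total} = \mathrm{FD\%}/100 \times \mathrm{scan\ area}$.

### Slabs and devices

Five CC slabs are compared, each an axial window below BM (boundaries
inclusive, measured along the axial axis, positive downward): the device's
automatic slab (0–20 µm on the swept-source device, 9–31 µm on the
spectral-domain device in both modes) and the fixed windows 11–21, 21–31,
31–41 and 16–31 µm. `extract_enface()` projects a volume over a slab by the
per-pixel mean of samples spaced at most one axial step apart, with linear
interpolation at fractional depths; a max projection is available behind a
flag. Which statistic the commercial devices use is not public, so the
projection is a configurable choice rather than a claim.

Device profiles cover a swept-source instrument (3 × 3 mm, 1024 × 1024 px,
≈2.93 µm/px) and a spectral-domain instrument (3 × 3 mm, 400 × 400 px,
7.5 µm/px) in non-averaged (V1) and four-volume (V4) modes. Note that the
default window radius of 4 px spans ≈30 µm on the SD grid but only ≈11.7 µm
on the SS grid; this is deliberately left unscaled because the standard
protocol applies the same pixel radius on both devices. A `radius_um`
convenience converts a physical radius by rounding.

## The synthetic generator

`generate_cc_pattern()` synthesizes a capillary mesh as band-pass-filtered
seeded Gaussian noise. The pass band is centred on the intercapillary
distance (ICD): vessel diameters average 16–20 µm with edge-to-edge gaps of
5–20 µm, so the ICD (one vessel plus one physiological void) is 21–40 µm and
the mesh's radially averaged power spectrum peaks inside that band. The field
is thresholded at an exact order statistic to the vessel/gap duty cycle, and
disc-shaped pathological voids (default radius 50 µm) are carved until the
true FD fraction is within ±0.01 of the target. Vessel pixels carry
intensities in $[0.55, 1]$; voids are exactly zero, so the true FD mask is
the zero-flow set and the true fraction is exact by construction.

Two details matter:

* **Reachable targets.** The geometric duty cycle (mean diameter over mean
  ICD, ≈0.59) implies an intrinsic mesh void fraction of ≈0.41. Carving can
  only add voids, so by default the thresholding quantile is
  `min(intrinsic void, target)`: any target in $[0,1]$ is reachable, and low
  targets simply produce a denser mesh. Passing a fixed `duty_cycle` pins the
  intrinsic void fraction, and targets below that floor raise an error that
  reports the achievable floor.
* **Rendering is point sampling.** The reference grid is 1024 px over 3 mm
  (≈2.93 µm/px) so swept-source rendering is resample-free. Coarser device
  grids are rendered by sampling the reference field at each pixel's beam
  position — the acquisition model of OCTA, where each en-face pixel is one
  A-scan. Interpolating resamplers (bilinear is available as an option) smear
  the vessel/void edges and systematically inflate measured FD% by several
  percentage points at low FD fractions; point sampling keeps the noise-free
  pipeline unbiased to within ±0.1 pp.

Volume averaging in the V4 mode is modeled purely as noise reduction: the
rendered noise is the mean of four independent draws, halving the noise SD.
No inter-volume motion is simulated. The structural channel is a constant
baseline reflectance of 0.8 before attenuation — arbitrary but fixed.

Drusen shadows are multiplicative attenuation discs applied identically to
both channels (the premise that makes inverted-structural compensation
meaningful): a flat core at `min_attenuation` (default 0.15) with a cosine
taper over the outer 30% of the radius, factor exactly 1 outside all
footprints. The deep core default reflects how strongly large soft drusen
attenuate the CC signal; empirically the Phansalkar classifier absorbs smooth
shading down to a factor of about 0.25 and misclassifies below it, so
realistic shadows must cross that level for the artifact — and hence the
value of compensation — to exist at all.

What the generator does *not* emulate: speckle statistics, B-scan physics,
motion artifacts, projection artifacts, RPE elevation geometry, or the
intensity distribution of real CC slabs (which is not publicly
characterized). Passing tests therefore demonstrate the correctness and
internal consistency of the processing chain and its qualitative behavior
under controlled perturbations, not quantitative agreement with any
particular patient cohort.

## Statistics layer

* `wilcoxon_signed_rank()` — paired two-sided test; zero differences are
  dropped; for $n \le 15$ the p-value is exact by full enumeration of the
  $2^n$ sign assignments (ties handled by average ranks), otherwise a normal
  approximation with tie and continuity correction. Its empirical type-I
  error at the cohort size $n = 23$ sits within [0.03, 0.07] at nominal 0.05.
* `icc2()` — ICC(2,1), the two-way random-effects, single-measure,
  absolute-agreement form, from the two-way ANOVA mean squares, with the
  F-based 95% interval of McGraw & Wong. Agreement of FD% across the five
  slab columns is computed per device.
* `repeated_measures_comparison()` — within-subject ANOVA with subject as
  random intercept (via `aov()` error strata), equivalent to the mixed linear
  model with a random subject factor under the complete balanced design the
  pipeline produces; one or two within-subject factors (device, slab).
* `tukey_posthoc()` — all-pairs comparisons on the effect's own
  repeated-measures error term via the studentized range distribution.

`build_comparison_tables()` assembles the summary outputs: a per-metric,
per-slab table of `mean ± SD` per device with pairwise-device p-values from
the paired Wilcoxon test (the test cited for the device comparisons), and a
per-device slab-by-slab p-value matrix for FD% from the Tukey post-hoc (the
stated post-hoc for slab pairs). Both conventions are documented here because
published reports often leave the mapping of tests to tables ambiguous. No
multiplicity correction beyond Tukey is applied; all tests are two-sided at
$\alpha = 0.05$.

## Numerical choices

* All neighborhood operations (Phansalkar window, Gaussian blur) use reflect
  padding with the edge pixel mirrored.
* The window SD is the population SD ($1/n$), matching the per-pixel
  brute-force definition the implementation is tested against.
* A pixel exactly equal to its threshold is FD; consequently a constant-zero
  image is 100% FD.
* Images are normalized by the dtype maximum at load (16-bit TIFF: 65535),
  never per-image min/max, so thresholding does not depend silently on an
  image's own range.
* Gaussian kernels are truncated at $3\sigma$ and renormalized.
* Linear interpolation at fractional slab depths; a 10-µm slab at 2-µm axial
  sampling would otherwise quantize badly.
* Component labeling builds the pixel-adjacency graph and takes its connected
  components; both connectivities run through the same route.
* The exact Wilcoxon two-sided p is $2\min(P(V \le v), P(V \ge v))$ capped at
  1, which keeps it symmetric under swapping the samples.

## Default study conditions

The default synthetic cohort draws a per-eye base FD fraction uniformly in
$[0.35, 0.55]$ (the range seen in intermediate AMD slabs). Each eye owns one
capillary mesh; all five slabs of that eye share it and differ only by their
carving target (base + per-slab shift, zero by default), so slab measurements
are strongly correlated within an eye, as in real eyes. Devices differ only
by grid and noise (SS 1024 px / noise SD 0.05; SD 400 px / 0.08, halved by V4
averaging). Per-eye shadow fields (default 4 drusen of 125 µm radius) are
shared across devices and slabs. Validation problem sizes — 10–20 scenes per
property, 5-eye pipeline cohorts, 2000 null replicates for test calibration —
were chosen as the smallest sizes at which the checked quantities are stable
to well below their tolerances.

## Known limitations

* The synthetic mesh is a spectral surrogate, not a vascular growth model;
  only its ICD spectral content, duty cycle and FD fraction are contractual.
* The Gaussian blur scale of the compensation step, the output scaling of
  the multiplication, and whether inversion acts on raw or display-stretched
  data are not standardized in the field; all three are explicit, logged
  parameters here.
* The devices' automatic-slab projection statistic is unknown; the mean is
  used, with max available.
* FD% uses all image pixels as the denominator; no artifact-exclusion ROI is
  implemented.
* ICC values computed on the default (neutral, slab-shift 0) cohort are close
  to 1 because slabs of an eye then differ only through processing noise;
  planted slab shifts lower them toward clinically reported ranges.
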