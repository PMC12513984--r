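# ccfd — choriocapillaris flow-deficit quantification from en-face OCTA

The choriocapillaris (CC) is the single capillary layer directly beneath
Bruch's membrane (BM); its perfusion is assessed on en-face OCT angiography
through *flow deficits* (FDs) — contiguous regions of the binarized flow
image lacking detectable flow. Quantitative CC results are notoriously
sensitive to the measurement pipeline: the axial slab projected, the device
and acquisition mode, the shadow-compensation step, and the binarization
parameters all shift the numbers. `ccfd` implements the standard processing
chain as tested, reusable R functions, together with a seeded synthetic
generator with exact ground truth, so that these sensitivities can be
quantified instead of argued about.

The package is aimed at researchers analyzing CC perfusion (e.g., in
age-related macular degeneration) and at methodologists studying
cross-device and cross-slab comparability.

## What it implements

* **Slabs** — the five standard CC slabs below BM per device (automatic:
  0–20 µm on swept-source, 9–31 µm on spectral-domain; plus 11–21, 21–31,
  31–41, 16–31 µm), and en-face projection of small volumes over a slab with
  linear depth interpolation (`slab_catalog()`, `extract_enface()`).
* **Compensation** — flow × Gaussian-blurred inverse of the structural slab,
  suppressing attenuation-induced false FDs under drusen
  (`invert_image()`, `compensate()`).
* **Binarization** — Phansalkar local adaptive thresholding over a circular
  window (radius 4 px default),
  `t = μ (1 + p e^(−qμ) + k (σ/r − 1))` with `(k, r, p, q) =
  (0.25, 0.5, 2, 10)`; FD iff pixel ≤ t (`phansalkar_threshold()`).
* **Particle metrics** — FD%, FD count, mean FD size (µm²) and total FD area
  (mm²) by connected-component analysis at 4- or 8-connectivity with
  physical-unit scaling (`quantify_fd()`, `apply_icd_size_floor()`).
* **Synthetic OCTA** — capillary meshes with intercapillary spacing in the
  physiological 21–40 µm band, planted flow voids at a controlled fraction,
  drusen-like shadowing, per-device grids and noise, optional 3-D volumes
  over a BM surface (`generate_cc_pattern()`, `shadow_field()`,
  `render_device_image()`, `generate_volume()`).
* **Statistics** — paired Wilcoxon signed-rank with exact small-sample p by
  enumeration, ICC(2,1) with F-based CI, repeated-measures ANOVA with
  subject as random intercept, Tukey post-hoc on the studentized range, and
  device-by-slab summary tables (`wilcoxon_signed_rank()`, `icc2()`,
  `repeated_measures_comparison()`, `tukey_posthoc()`,
  `build_comparison_tables()`).
* **Pipeline** — simulate → compensate → binarize → quantify → compare as a
  seeded, YAML-configurable, deterministic run (`run_pipeline()`); a thin
  command-line front-end lives at `inst/cli/ccfd.R`.

## Worked example

```r
library(ccfd)

# ground truth: capillary mesh at 45% flow-deficit fraction
gt <- generate_cc_pattern(vessel_params(target_fd_fraction = 0.45, seed = 42))
gt
#> Synthetic CC ground truth: 1024 x 1024 px (2.93 um/px), FD fraction 0.4453

# image it with the 400 px spectral-domain profile under 4 drusen shadows
pair <- render_device_image(gt, shadow_field(1024, n_drusen = 4, seed = 42),
                            device_profile("sd_v1"), seed = 42)

# compensate, binarize, quantify
comp <- compensate(pair$flow, pair$structural, compensation_params(),
                   pair$pixel_size_um)
fd   <- phansalkar_threshold(comp, phansalkar_params(radius_px = 4),
                             pair$pixel_size_um)
quantify_fd(fd)
#> FD metrics: FD% = 44.85, count = 2452, mean size = 1646.32 um^2, total area = 4.037 mm^2
```

Despite noise and drusen shadowing, the measured FD% (44.85) recovers the
planted ground truth (44.53%) to within half a percentage point; the four
metrics are linked by `count × mean size = total area × 10⁶` and
`total area = FD%/100 × 9 mm²` exactly.

Paired device comparisons use the exact signed-rank test:

```r
a <- c(44.1, 46.3, 43.2, 47.9, 45.5, 44.8, 46.0, 45.1)   # device A FD%
b <- a + c(9.8, 10.4, 11.0, 9.1, 10.9, 9.7, 10.2, 10.6)  # device B: ~+10 pp
wilcoxon_signed_rank(a, b)[c("statistic", "p_value", "method")]
#> $statistic [1] 0   $p_value [1] 0.0078125   $method [1] "exact-enumeration"
```

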