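---
title: "Quantifying spatial organization in a dual-species phototrophic biofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial organization in a dual-species phototrophic biofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early biofilms of a filamentous, N~2~-fixing cyanobacterium and an
eGFP-tagged heterotrophic *Pseudomonas* rod organize in a characteristic
way: the rods form a *seeding layer* directly on the attachment surface
and cluster around the cyanobacterial filaments, and both features are
stronger when the cyanobacterium must fix molecular nitrogen (no nitrate
in the medium). `duofilm` turns the imaging workflow that quantifies
this organization — dual-channel confocal z-stacks, isosurface-style
segmentation with cross-channel masking, depth-stratified biovolume
percentages, intensity profiles and co-localization, plus proteome
ranking and CFU accounting — into tested, scriptable code. Because the
original raw images are not deposited, every imaging stage is exercised
against synthetic phantoms with voxel-level ground truth.

## Conventions

* Arrays are `(ny, nx, nz)`; slice `k` spans `[(k-1)·dz, k·dz)` with its
  voxel centers at `(k-0.5)·dz`. `z = 0` is the attachment surface.
* `voxel_spacing` is `(dz, dy, dx)` in µm; intensities are 8-bit (0–255).
* Depth segments are half-open slabs `[z_lo, z_hi)`; a voxel belongs to
  the segment containing its center (no fractional voxels, sharp
  transitions at boundaries). The standard slabs are 0–10, 10–20,
  20–30 µm.
* Thresholds are strict (`>`): equality at the threshold excludes.

## The phantom generator

`generate_phantom()` builds a two-channel stack from explicit geometry:

* **Filaments** (red channel) are random-walk tubes: fixed step length
  (2 µm), Gaussian heading perturbation (`filament_step_sd`, 0.5 µm per
  step), reflected at the domain boundary, starting near the surface
  with an upward bias — the phototroph grows toward the light-facing
  side.
* **Rods** (green channel) are capsules (cylinder plus hemispherical
  caps, end-to-end length `rod_length`). A fraction
  `seeding_layer_fraction` has its centroid inside the seeding layer
  (z < 10 µm); a fraction `coloc_fraction` is placed with centroid
  within `coloc_radius` of a filament axis, touching but not
  overlapping the filament tube. The remaining rods are rejection-
  sampled *away* from the filaments (beyond the 5 µm scoring radius
  plus the rod extent), so the planted co-localized fraction is a clean,
  recoverable ground truth — without the exclusion, uniformly placed
  rods would sit near filaments by chance and the parameter would not
  be identifiable at this field size.
* Truth masks are recorded at this point, before any optics: a voxel is
  true when its center lies inside an object. Per-segment true volumes
  are exact voxel counts times the voxel volume, so they are invariant
  to all noise settings.
* **Degradation** then runs intensity assignment (overlapping objects
  take the maximum — cells are opaque, not additive) → exponential
  depth attenuation from the detector side (the high-z face; factor
  `exp(-(z_max - z)/attenuation_length)`) → separable Gaussian PSF →
  Poisson resampling (`poisson_scale` photons per intensity unit) →
  additive Gaussian read noise → clipping and rounding to 0–255.

### Default study conditions

The defaults describe one imaged field at phantom scale. No voxel size
or field of view is reported for the original 10×/1.1 W acquisitions,
so the grid is configuration, not a claim: 96 × 96 × 32 voxels at
(dz, dy, dx) = (1, 0.5, 0.5) µm — a 48 × 48 µm field, 32 µm deep,
modestly oversampled so a single rod spans ≥ ~10 voxels and voxel-level
recovery is meaningful. Two filaments of radius 2 µm (30 × 2 µm steps)
and 400 rods of 3 × 1.2 µm give a surface-slab green biovolume of a few
percent, matching the reported 3–10% surface coverage range; 80% of
rods seed the surface layer and 40% co-localize within 4 µm of a
filament axis. The PSF sigma is (0.5, 0.25, 0.25) µm (z, y, x) — on the
order of a high-NA water objective, and deliberately not smaller than
half a voxel, which the generator rejects as unresolvable. Attenuation
length 150 µm (mild over a 30 µm biofilm), emitted intensities 180
(red) and 150 (green), shot noise at 1 photon per intensity unit and
read noise SD 5 give an in-object SNR of roughly 10.

What the phantoms do **not** emulate: EPS, heterocysts, filament
branching or bundling, spatially varying background, optical
aberrations beyond a Gaussian PSF, or registration error between time
points. Passing recovery tests therefore demonstrates that the
*quantification chain* is correct and well-conditioned under a
realistic noise model — not that the specific published biovolume
numbers are reproduced, which would require the undeposited raw images.

## Segmentation

The original workflow thresholds an IMARIS "quality" measure, which is
not documented in enough detail to reimplement; `duofilm` interprets it
as a smoothed-intensity threshold on the 8-bit scale. `segment_red()`
thresholds the (optionally Gaussian-smoothed) red channel at
`red_threshold` (default 30). `segment_green()` first zeroes every
green voxel inside the red mask (`mask_green_by_red()` — the guard
against counting overlapping signal twice), then smooths, then
thresholds per depth slab with that slab's threshold (defaults 14, 12,
10 for 0–10, 10–20, 20–30 µm — shallower slabs demand more signal).
Voxels inside the red mask are excluded from the green mask outright:
smoothing can bleed masked intensity back across the boundary, and the
exclusivity guarantee (`green ∧ red = ∅`, always) takes precedence.
Components smaller than `min_object_voxels` (default 8, suppressing
shot-noise speckle; set 1 for oracle tests) are removed by
26-connectivity labelling. Voxels whose center falls in no configured
slab are excluded and tallied in `unsegmented_voxels`.

### Matched parameters for recovery experiments

For ground-truth recovery the thresholds are tied to the generator's
amplitudes (`matched_segmentation_params()`): red at half the red
amplitude — filaments are thick relative to the PSF, so the
half-amplitude contour tracks the true boundary — and green at 0.3× the
green amplitude, because rods are only 1–2 PSF widths thick and retain
roughly 60–70% of their nominal amplitude after blurring; half of
*that* is the boundary-tracking level. Extra smoothing is off (the PSF
already band-limits, and the noise floor after thresholding and
small-object removal is negligible). Recovery error is flat across
green fractions 0.25–0.40, so the rule is not a knife-edge. Under the
default noise model this recovers every per-segment volume within 10%
(typically ~1% on average); in the noise-free limit (PSF, attenuation
and noise off, `min_object_voxels = 1`) recovery is exact
(Jaccard = 1 over the analyzed 0–30 µm region).

## Quantification and statistics

`biovolume_by_segment()` reports, per slab, the cell volume (mask
voxels with center in the slab × voxel volume), the slab volume, and
their ratio as a percent — each slab's total volume counts as 100%.
Summed over disjoint slabs the cell volumes conserve the total masked
volume exactly (integer voxel counts). Ratios (`ratio_ps_to()`) are
computed per replicate and then summarized, matching per-image box
plots, rather than as a ratio of means; records with zero red
biovolume are flagged undefined and excluded from summaries with a
logged count.

Statistical choices, where the source leaves room:

* **Welch's** unequal-variance t-test (two-sided, Welch–Satterthwaite
  df) rather than the pooled-variance variant — the published box plots
  show clearly unequal spreads between depths and conditions, and only
  "T-test" is stated. Implemented from the closed form with its own
  degenerate-input guards; `stats::t.test` serves as an independent
  cross-check in the tests.
* **Quantiles** by linear interpolation (type 7); the plotting
  software's default is unverifiable. Whiskers are Tukey: most extreme
  points within 1.5 × IQR of the quartiles, the rest listed as
  outliers.
* **No multiple-testing correction** in the headline numbers (raw
  p-values, as published); the analysis scripts add a clearly labelled
  Benjamini–Hochberg column as an extra.

## Profiles, co-localization, retention

`lateral_profile()` averages each channel over one lateral axis and a
z-range, per position along the other axis — a dense version of the
published per-position intensity graphs. `coloc_fraction()` scores the
fraction of green voxels within `radius` (default 5 µm ≈ one rod
length; no radius is published) of the red mask, using an exact
anisotropic Euclidean distance transform in physical units.
`retention_analysis()` splits the before-time-point green voxels into
co-localized and loose classes by the same distance rule and reports
the fraction of each class still present after — on aligned grids only;
registering real time series is out of scope, phantom pairs are
generated aligned.

## Proteome ranking

Within each sample, proteins are ranked by abundance, rank 1 for the
most abundant. Ties take the average of the tied positions (the source
does not mention ties; a competition policy is available by flag). ND
means "no abundance value for this sample" — a zero abundance is
invalid input, not ND. Per condition, replicate ranks are summarized as
mean ± sample SD; whether the published "±" is a sample SD or a
half-range for n = 2 is not stated (they differ by √2), so sample SD is
the default with `half_range` available. Condition-exclusive proteins
require detection in every replicate of one condition (configurable)
and none of the other. The FDR confidence category is carried through
as metadata; FDR estimation itself is upstream. Optional
internal-standard normalization divides each sample by a named
reference protein's abundance — ranking is scale-invariant, so this
affects only exported values. The synthetic generator plants a known
exclusive set into log-normal abundance tables (meanlog = log(10⁶),
sdlog = 2, a wide label-free-like dynamic range) and is noise-free by
default so recovery is exact.

## CFU accounting

`cfu_per_liter()` is the track-dilution formula
`colonies × dilution / volume`. `detachment_summary()` forms
resident:detached ratios per condition, with a first-order
(delta-method) standard error from the reported input SDs as an
optional extra. On the packaged reference means the ratios are ≈486
(N~2~-fixing) and ≈171 (nitrate-fed), a fold of ≈2.8 — the source text
calls this "almost twice" in one place and "three times" in another;
the package reports the computed value and the analyses assert only
the ≥2 bound.

## Numerical and design notes

* 26-connectivity in 3-D; smoothing sigmas are specified in µm and
  converted per axis via the voxel spacing.
* The distance transform is the exact squared-EDT
  (Felzenszwalb–Huttenlocher) run per axis with anisotropic spacing.
* Half-up rounding (`floor(x + 0.5)`) for per-day object counts;
  per-day seeds are `base_seed + 10007 × day` (documented and fixed),
  replicate r adds `271 × (r-1)`.
* Degenerate inputs error loudly: empty samples, zero plated volume,
  zero denominators, segments outside the stack (named in the
  message), shape mismatches, missing channels.
* Problem sizes in the shipped tests and analyses — 96² × 32-voxel
  phantoms, 5-phantom recovery batches, 2,300-protein tables — are the
  package's chosen phantom scale: large enough that per-segment counts
  are in the thousands of voxels and recovery tolerances are
  meaningful, small enough that the full suite re-runs in well under a
  minute per module.

## Known limitations

* The segmentation operator is an interpretation of an undocumented
  commercial "quality" threshold; absolute agreement with that tool is
  neither claimed nor testable.
* Biovolume recovery tolerances are established on phantoms; real
  stacks add background, aberrations and EPS autofluorescence that the
  phantom model does not contain.
* Retention analysis assumes aligned grids; drift or stage error in
  real time series must be corrected upstream.
* The proteomics module consumes post-search abundance tables; nothing
  is inferred about peptide-level evidence.
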