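---
title: "Spherical modelling of vesicle distributions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical modelling of vesicle distributions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesdist)
```

## The model and its assumptions

`vesdist` treats a cell as approximately spherical and asks a single
question of a one-channel fluorescence z-stack: *at what (size-normalized)
radial distance from the cell center does the vesicle signal sit?* The
answer — a weighted distance distribution — distinguishes a homogeneous
cytoplasmic dispersion of vesicles (unimodal) from a pathological state in
which vesicles arrest near the plasma membrane (bimodal: a perinuclear peak
plus a membrane-adjacent peak).

The approach deliberately avoids segmentation. There is no nucleus
detection, no membrane mask, no per-vesicle tracking. Everything derives
from a global intensity threshold and intensity-weighted moments:

* **Background model.** Camera background is modelled as a Gaussian whose
  parameters are read off the pooled intensity histogram: the mean `mu` from
  the histogram mode, and the variance from the mean squared deviation of
  intensities *below* the mode. Because genuine fluorescence only adds
  intensity, signal contaminates the right tail exclusively, and for a
  symmetric background law `E[(Y - mu)^2 | Y < mu] = sigma^2`, so the
  left-tail estimator is consistent regardless of how much signal the image
  contains.
* **Threshold.** `theta = mu + n_sigma * sigma`. The default `n_sigma = 10`
  is deliberately conservative; the shape of the resulting distance
  distributions is insensitive to this choice over a wide range (the test
  suite checks `n_sigma` in {5, 10, 15}). STED frames use a global
  `mean + n_sigma * sd` threshold with `n_sigma = 1` instead, because their
  sparse bright events leave global moments close to the background moments.
* **Weights.** Each suprathreshold pixel contributes its threshold excess,
  `w_i ∝ [y_i > theta](y_i - theta)`. The strict inequality matches the
  Iverson bracket; pixels exactly at `theta` have zero raw weight under
  either convention, so the choice is observationally irrelevant but fixed
  for determinism. Weights are normalized to sum 1 internally — the
  definition is only proportional, and normalization fixes a representation.
* **Center and size.** The weighted center of mass estimates the cell
  center; the radius of gyration `R_g` (weighted RMS distance from the
  center) estimates cell size. Dividing distances by `R_g` removes cell-size
  variation, which otherwise dominates population comparisons.

The assumptions to keep in mind: the cell is roughly isotropic around its
center of signal mass; the background is a single Gaussian (no flat-field
gradients); and the signal of interest is punctate and bright relative to
`theta`. Strongly elongated cells (e.g. adult rod-shaped cardiomyocytes)
violate the first assumption and would need an ellipsoidal extension.

## Coordinates, spacing and units

Voxel indices are 0-based; the pixel center of voxel `(k, j, i)` is the
point `(k, j, i)` in index space, multiplied componentwise by the voxel
spacing `(dz, dy, dx)` for physical distances. The default spacing is the
isotropic 1, which reproduces distance computations in raw pixel units when
no metadata is available; spacing stored by `write_stack()` (or supplied
explicitly) switches the same code to physical units, including anisotropic
confocal geometries where the z-step is an order of magnitude coarser than
the pixel pitch. Whether distances should span z at all is exposed as
`planar = TRUE` in `cell_geometry()` for a per-layer 2D comparison; the
default is full 3D.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n_sigma` (confocal) | 10 | – | threshold multiplier over background sigma |
| `n_sigma` (STED) | 1 | – | multiplier over the global sd |
| `histogram_bins` | 256 | – | background histogram bins for float data (integer data use unit bins) |
| `downsample_factor` | 2 | – | in-plane block-mean sampling rate |
| `bins`, `grid_max` | 100, 2.5 | scaled distance | common grid for scaled histograms |
| `cutoff` | 1.0 | scaled distance | membrane-fraction boundary |

The common grid `[0, 2.5] x 100` bins is a package choice: a fixed grid is
required for population averaging and PCA, the support of scaled distances
is bounded near `sqrt(5/3) ≈ 1.29` for homogeneous cells and below ~2 for
membrane-arrested ones, and mass beyond the grid is clipped into the last
bin and reported as an explicit overflow fraction. The membrane-fraction
cutoff of 1 (mass beyond one radius of gyration) is likewise a documented
package convention, not a biological constant; `membrane_fraction()` takes
any cutoff inside the grid and is monotone in it.

## Numerical choices

* **Histogram mode refinement.** The raw argmax of a Poisson-noisy
  histogram has a flat-top ambiguity: with background sd ~150 and 1e6
  pixels, unit-bin counts near the peak differ by less than their own
  sampling noise over a ±30-intensity-unit plateau, so the literal "highest
  bin" wanders by a few percent of `mu` between realizations. The estimator
  therefore (a) lightly smooths the histogram (boxcar of about 1/256 of the
  occupied range) before locating the maximum and (b) refines the mode with
  a count-weighted quadratic fit to the log-counts within one provisional
  sigma of the peak — a Gaussian is an exact parabola in log space, and the
  window ends far left of the (>10 sigma) signal tail. The fit is performed
  in mode-centered coordinates for conditioning, which also makes the
  estimator exactly shift-equivariant for integer data. Both behaviors are
  optional (`smooth_window = 1`, `refine = FALSE` give the plain argmax);
  recovery at the defaults is ~0.05% in `mu` and ~0.3% in `sigma` at 1e6
  pixels with 7% signal.
* **Sigma as a population moment.** The left-tail variance divides by the
  count, not count − 1: it is a plug-in moment, not an unbiased sample
  variance, and at typical pixel counts the distinction is far below other
  error sources.
* **Binning convention.** Histogram bins are half-open `[e_b, e_{b+1})`
  with the last bin closed; ties at `theta` are excluded by the strict
  inequality. Both conventions are fixed so results are bit-reproducible.
* **PCA.** Density rows are column-mean centered, not variance-scaled (all
  bins share units); components come from the SVD with a deterministic sign
  convention (the largest-magnitude loading of each component is positive),
  so scores are reproducible across platforms. Explained fractions are
  singular values squared over total centered variance.
* **Peak detection.** Curves are smoothed with a 3-bin moving average
  (shrinking windows at the edges) before strict local maxima are located;
  peaks are filtered by topographic prominence, which suppresses
  sampling-noise wiggles without a hard height threshold.
* **Degenerate inputs.** All-constant stacks (no background dispersion),
  stacks with no pixel below the mode, cells with no suprathreshold pixel,
  and cells with `R_g = 0` are rejected with typed QC errors; the pipeline
  driver records them in an exclusions file with the reason rather than
  dropping them silently.

## What the synthetic generator emulates

`generate_cell()` renders: a Gaussian camera background (mean 1861.63, sd
147.70 — the regime of a 16-bit confocal detector); vesicles of finite size
(`vesicle_sigma = 3.5` px, roughly a 0.8 µm FWHM endosome at 0.1 µm
sampling) blurred by a PSF (`psf_sigma` 2.5 confocal-like, 0.6 STED-like)
and rendered as separable voxel-integrated Gaussians; lognormal per-vesicle
amplitude jitter around a mean peak of 60 background sigmas; 16-bit
quantization and clipping. Spatial models place vesicle centers uniformly in
the cell volume (homogeneous), in a membrane-shell/perinuclear-core mixture
(`membrane_weight` 0.5 for the arrested phenotype, 0.1 for a rescued
intermediate), or purely on the shell.

Three generator choices deserve explanation:

* **Spherical default, coarse z.** The default cell is a sphere of radius
  80 px inside a 16 × 256 × 256 stack; the generator picks a z-step
  (`dz ≈ 11.9` px/layer) so the sphere spans 90% of the 16 layers and
  records it in the stack's spacing metadata, exactly like a real confocal
  stack with fine pixels and a coarse z-step. An `axial_squash < 1` option
  flattens the cell for adherent geometries, but strong flattening makes
  every disposition effectively two-dimensional, where the mass beyond one
  radius of gyration is nearly the same (~0.46–0.47) for homogeneous and
  bimodal cells alike — the membrane-fraction readout only discriminates in
  approximately isotropic geometry, which is also the geometry the spherical
  model assumes.
* **Rim-concentrated membrane shell.** Shell directions are sampled
  uniformly on the unit sphere *before* any axial squash. Under flattening,
  area-uniform sampling of the squashed surface would put most "membrane"
  vesicles on the flat top and bottom faces; sampling the spherical angle
  keeps them at the lateral rim, which is where membrane-arrested endosomes
  appear in z-projections of real cells.
* **Bright, finite-size vesicles.** With a mean peak of only ~20 background
  sigmas, the 15-sigma threshold of the robustness checks would sit at 75%
  of a typical peak, where the integrated excess of a Gaussian spot scales
  like `log(peak/theta)^{5/2}` — hypersensitive, so per-vesicle weights (and
  the suprathreshold pixel fraction, then below 1%) would churn with
  `n_sigma`. At 60 sigmas (~10,700 counts over a 1,862-count background,
  far from 16-bit saturation) with 3.5 px intrinsic size, the default stacks
  have 3–7% suprathreshold pixels — the regime of real immunostained
  puncta — and their distance distributions move by less than 0.09 in L1
  across `n_sigma` in {5, 15}.

What the generator does **not** emulate: photon shot noise (background is
additive Gaussian only), realistic PSF shapes (no Gibson–Lanni, no axial
elongation), flat-field or depth-dependent attenuation, autofluorescence
gradients, cell-shape variety beyond the squashed sphere, and vesicle
motion. Passing tests on synthetic data therefore demonstrate that the
*estimators* recover known ground truth under the stated image-formation
model — not that the model captures every property of real microscope data.

## Problem sizes used in the tests

The validation suite runs, per check: 50 random 16 × 32 × 32 stacks against
brute-force loop oracles (exact agreement); a 72³ uniform-ball phantom with
~113,000 interior voxels (`R_g/R` within 1% of `sqrt(3/5)`, mean scaled
distance within 0.02 of `(3/4) sqrt(5/3)`); background recovery on 1e6-pixel
stacks over 10 seeds; threshold and down-sampling robustness on 10
default-size cells; homogeneous vs membrane-arrested cohorts of 30 + 30
cells over 10 seeds (membrane-fraction ordering, bimodality of the mean
curve, ≥80% PC1 separation); a rescue contrast of 40 + 40 cells over 10
seeds (membrane fraction and ≥50% outer-peak mass reduction); and 10 paired
STED/confocal renderings of identical ground truth (event-count ordering).
These sizes were chosen to make sampling error small relative to the margins
being tested while keeping the full suite runnable on a laptop.

## Known limitations

* The spherical approximation degrades for elongated or highly irregular
  cells; an ellipsoidal coordinate system would be the natural extension.
* The center of mass is signal-weighted, so a grossly asymmetric vesicle
  distribution biases the center estimate toward the signal; the scaled
  distribution remains well-defined but its "center" is then not the
  geometric cell center.
* The membrane fraction conflates any outward-shifted mass with membrane
  arrest; it is a summary statistic, not a classifier.
* Group comparisons are descriptive (mean ± SEM, difference curves, PCA
  overlays). Cell-to-cell variability in reprogrammed cell models is large,
  and no significance claims are made or implied.
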