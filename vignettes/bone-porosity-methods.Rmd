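---
title: "Methods: voxel-wise BMD-PI analysis of whole bones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise BMD-PI analysis of whole bones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(porindex)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package. The README shows the user-facing workflow;
here the emphasis is on *why* each stage is built the way it is, and what
the validation on synthetic data does and does not establish.

## The measurement model

Two modalities observe the same bone.

**Quantitative CT.** Grey values are assumed affine in mineral density,
`grey = g0 + g1 * BMD`, with `BMD` in mg hydroxyapatite (HA) per cm³. A
calibration phantom with rods of known density lies in the field of view;
`fit_calibration()` regresses the known densities on the per-rod mean grey
(ordinary least squares; the exact line when only two rods are present) and
`apply_calibration()` maps the whole volume. Density is regressed on grey,
not the reverse, so application is a direct affine transform of the image.
Negative calibrated values are retained by default: they are legitimate
noise excursions, and clamping them would bias the voxel-wise regression
that follows.

**Dual-echo UTE MRI.** Bone water splits into a collagen-bound pool (BW)
with a very short effective transverse relaxation time and a pore-water
pool (PW) with a much longer one. The two-pool signal at echo time `TE` is

```
S(TE) = A_BW (1 - phi) exp(-TE / T2*_BW) + A_PW phi exp(-TE / T2*_PW)
```

with `phi` the pore fraction. At the long echo (default 2.52 ms) the bound
pool has decayed by roughly three orders of magnitude (T2\*_BW default
0.39 ms) while pore water (T2\*_PW default 10 ms) retains most of its
signal, so the echo ratio

```
PI = 100 * S(TE_long) / S(TE_short)
```

is a monotone proxy for `phi`. `compute_pi()` evaluates the ratio wherever
the short echo exceeds a background floor (default: five times the noise
SD estimated from the eight corner patches of the volume); other voxels are
invalid and carry `NaN`. Values above 100 % are possible under noise and
are deliberately not clipped — clipping would bias the regression — but
they are counted and reported.

**The comparison.** After registration, every CT-grid voxel in the condyle
region of interest contributes a (BMD, PI) pair, and `regress_specimen()`
fits `PI = intercept + slope * BMD` by OLS, reporting the slope (PI % per
mg HA/cm³), its standard error, Pearson r, and the two-tailed p from
`t = r sqrt((n-2)/(1-r^2))` — algebraically identical to the slope t-test
for simple OLS. Study-level statistics (`build_study_table()`) summarise
per-limb r by group (forelimb/hindlimb, left/right, LF/RF, LH/RH), test
normality with the Jarque–Bera statistic (`n/6 (S^2 + (K-3)^2/4)` against
chi-squared with 2 df), and compare groups with a two-sample t-test —
Student pooled-variance by default, Welch as an option.

## Segmentation chain

The bone is isolated on the CT volume and the mask transferred to the
analysis:

1. **Median filter**, spherical neighbourhood of radius 2 voxels (33
   voxels), truncated at volume edges.
2. **Bernsen local threshold**: in a centred cubic window (default edge 50
   voxels for clinical-scale volumes; 13 for the package's scaled-down
   synthetic study), a voxel is foreground when the window contrast
   `hi - lo` reaches the contrast threshold and the voxel is at least the
   window mid-grey `(hi + lo)/2`. Low-contrast regions are classified
   wholesale by comparing the window mid-grey to the volume's global
   mid-grey. The global mid-grey is the midpoint of the 0.5 % and 99.5 %
   intensity quantiles rather than the raw min/max: over ~10⁶ noisy voxels
   the raw extremes are order statistics of the noise, and a single
   excursion could move the classification of every low-contrast region.
3. **Largest 26-connected component**, with ties broken toward the
   component containing the lowest linear voxel index (a documented,
   deterministic rule).
4. **Condyle crop**: an axis-aligned cut plane at a stated fraction of the
   bone's bounding-box extent along its long axis (the axis of maximal
   physical extent), keeping the distal side. This replaces interactive
   diaphysis removal with a reproducible parameter.

The contrast threshold must sit between the cortical/trabecular grey
contrast (which should *not* split the bone) and the bone/background
contrast (which must). For the synthetic study's grey model the pipeline
default is 1150 grey units; for other data it must be chosen from the
histogram. The slicewise (2D window) option reproduces per-slice
processing of 2D tools; the 3D window is the default.

## Registration

`register_affine()` maximises joint-histogram mutual information (MI, in
bits, 32 bins per image over each image's global range) over a
translation–rotation–log-scale–shear parameterisation, with a coarse-to-
fine block-mean pyramid (factors 4, 2, 1) and cyclic one-dimensional line
searches (derivative-free, fully deterministic). Three choices matter and
each fixes a concrete failure mode observed during development on
synthetic pairs with known misalignment:

- **Partial-volume joint histogram.** Binning interpolated moving values
  makes MI piecewise-jagged in the transform at the ~10⁻³-bit scale — the
  same magnitude as the rotation signal per degree for blob-like anatomy —
  and line searches stall on the jitter. Distributing each sample's
  trilinear weights over the eight moving-image neighbours (Maes-style
  partial-volume interpolation) makes the metric smooth.
- **Pose pivoted at the fixed image's intensity centroid.** About an
  arbitrary centre, a rotation step displaces the anatomy and must be
  co-compensated by translation; coordinate descent crawls along that
  diagonal valley. About the centroid the two parameter classes decouple.
- **Rigid first, affine refinement last.** For an ellipsoidal bone a small
  rotation is nearly exchangeable with an anisotropic scale-plus-shear, so
  the full 12-parameter search can soak a genuine rotation into the scale
  terms. The rigid subset is optimised through the whole pyramid; the
  remaining six affine parameters are released only at the finest level
  inside a ±0.03 trust region. The rotation search keeps its full ±8°
  range at every level because the smoothed coarse levels constrain
  rotation only weakly.

The `init` argument takes the place of a manual rigid pre-alignment;
identity is sufficient within the coarse-level capture range (several mm
and degrees). `align_pi_to_ct()` then resamples PI linearly onto the CT
grid and the validity mask by nearest neighbour; a voxel is valid only if
its nearest source voxel was valid and the interpolated value is finite.

A genuine limitation, measured by profiling MI along the rotation axis at
full resolution: for a single specimen of blob-like anatomy the metric's
true maximum can sit up to ~1° from the true rotation about the bone's
long axis. Translation is recovered to small fractions of a voxel; the
rotation figure is an identifiability property of the data, not of the
optimiser, and motivates the median-across-specimens framing of the
registration checks in the test suite.

## The synthetic study

`phantom_spec()` defines a condyle-like bone — an ellipsoid cap (default
semi-axes 9 × 7 × 8 mm, wider mediolaterally than dorsopalmarly as a
distal condyle is; the asymmetry also makes long-axis rotation observable
to registration) joined to a cylindrical shaft (radius 5 mm, length
14 mm), with a cortical shell (default 2 mm). Porosity defaults are 0.035
in the shell and 0.793 in the trabecular core — the two compartments'
conventional magnitudes — plus band-limited spatial variation (white noise
laid down at a 3 mm correlation length and linearly upsampled, SD 0.05).
Both the shell thickness and the correlation length are deliberately
resolvable at the 0.66 mm MR voxel: structure finer than the MR sampling
cannot be recovered by *any* analysis, and a generator dominated by
sub-voxel structure would make ground-truth recovery unattainable in
principle rather than testing the pipeline.

BMD couples negatively to porosity, `BMD = rho_max (1 - coupling * phi)`
with `rho_max = 1200` mg HA/cm³, plus Gaussian noise representing
biological decoupling (mineralisation variation, marrow content) between
the two quantities. The default coupling of 0.5 places cortical bone near
1180 and trabecular bone near 720 mg HA/cm³ — appropriate for a densified
athletic condyle, where the trabecular compartment does not fall to the
full pore-volume deficit. CT rendering adds the affine grey model
(`g0 = 40`, `g1 = 1.8`), three calibration rods (0, 200, 400 mg HA/cm³)
outside the bone, a flat soft-tissue background (grey 60) and global
detector noise (SD 25). MR echoes are evaluated from the two-pool model on
the CT grid, sampled onto the 0.66 mm isotropic MR grid through the
inverse of the true alignment transform (default: translation
(3.2, −1.5, 0.8) mm plus 5° about the long axis), and perturbed with
additive Gaussian noise (SD 0.01 in units of the short-echo bone signal;
a Rician option exists, but at these signal-to-noise ratios the difference
is second order and the Gaussian keeps the analytic correlation-
attenuation formula exact). CT and MR grids intentionally differ
(0.273 × 0.273 × 0.4 mm, 96³, versus 0.66 mm isotropic, 64³) so the
resolution-matching step of registration is genuinely exercised.

`study_plan()` lays out six horses × four limbs with one right forelimb
excluded (23 analyzable specimens, the shape of the cadaver study), and
draws per-limb heterogeneity: coupling uniform on (0.30, 0.45), BMD
decoupling noise uniform on (60, 150) mg/cm³, MR noise uniform on
(0.005, 0.01). The BMD-noise range is what spreads the per-limb
ground-truth correlations over a wide band; its upper end is capped where
the implied CT image noise would start to defeat the Bernsen segmentation
chain — a property of the modeled workflow that real protocols share.
Every field is a deterministic function of the specification and a seed.

**What passing the synthetic checks shows, and what it does not.** The
generator emulates the statistical structure the analysis assumes: a
two-compartment porosity field, affine CT physics, two-pool MR signal,
misalignment, and noise. It does not emulate partial-volume point-spread
functions, k-space/radial readout artefacts, fat signal, beam hardening
or scatter, cartilage and soft tissue, or real anatomical shape
variation. Recovery of ground truth here validates the pipeline's
internal consistency and numerics — not the biological claim, which only
real specimens can test.

## Numerical choices and conventions

- Index order `(i, j, k)` with `i` fastest; 0-based indices in all
  world-coordinate formulas; voxel-centre convention;
  `world = origin + direction %*% (index * spacing)`. Synthetic data are
  always axis-aligned; non-orthonormal direction matrices are rejected at
  read time.
- Resampling outside the moving volume fills with 0 (the background level
  of both modalities); masks use nearest-neighbour.
- NIfTI doubles round-trip bit exactly; the format stores voxel spacing in
  single precision, so geometry equality is asserted at 1e-7.
- The OLS/Pearson/slope-SE formulas are implemented from their closed-form
  sums (one pass over up to ~10⁵ voxels) and are tested against
  `stats::lm()`/`stats::cor.test()` to 1e-10 relative; the group t-tests
  call `stats::t.test()` directly.
- Correlation-strength labels band |r| after rounding to two decimals:
  below 0.20 very weak, then weak, moderate, strong, very strong at 0.20
  steps.
- Report display rounds half away from zero at printed precision; machine
  outputs always carry full precision.
- Degenerate inputs have defined behaviour throughout: empty masks error
  in calibration and diagnostics but yield an empty mask from
  `largest_component()` (logged semantics, not an error); constant images
  give MI 0; a two-point calibration is the exact line; component-size
  ties break to the lowest linear index.

## Problem sizes

The test suite exercises unit-level properties on 48³ CT / 32³ MR phantoms
(a quarter-scale condyle, seconds per stage) and the study-level checks on
the full 96³ CT / 64³ MR six-horse study; the latter is also what
`scripts/acceptance.R` runs. These sizes are the package's reference
configuration for the synthetic study; all stages scale to clinical
512²-matrix volumes, with the local-threshold window returned to its
50-voxel clinical default.

## Known limitations

- The per-limb published table is transcribed at printed precision; its
  group p-values recomputed from 2-decimal r values differ from the
  originally computed ones (which used unrounded r), so the package
  asserts the significance pattern rather than exact p reproduction.
- Rotation about the bone's long axis is weakly identified by MI for
  near-axisymmetric anatomy (see above).
- No cortical/trabecular sub-segmentation: the condyle is analysed as one
  compartment, and the single pooled regression mixes two populations
  whose within-compartment correlations are weaker than the pooled one.
- No deformable registration; specimens are assumed rigid-to-affine
  related across modalities.
- The PI formula is used as an index, not a calibrated pore-fraction
  estimate; no T2* fitting or bicomponent decomposition is attempted.
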