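# porindex

Voxel-wise analysis of bone quality from paired quantitative CT (QCT) and
dual-echo ultra-short-echo-time (UTE) MRI, for whole distal limb bones such
as the equine third metacarpal/metatarsal condyle.

Cortical and trabecular bone carry two labile water pools: collagen-bound
water (BW, T2\* well under a millisecond) and pore water (PW, T2\* of
several milliseconds). A dual-echo UTE acquisition samples the signal

S(TE) = A_BW (1 − φ) e^(−TE/T2\*_BW) + A_PW φ e^(−TE/T2\*_PW),

so at a long echo time only pore water survives, and the **porosity index**

PI = 100 % × S(TE_long) / S(TE_short)

is an indirect map of the pore fraction φ. CT grey values, calibrated
against hydroxyapatite phantom inserts by the linear map
BMD = a·grey + b, give **bone mineral density** (mg HA/cm³). Because
mineral occupies what pores do not, BMD and PI should be inversely related
voxel by voxel; the strength of that relationship — the per-specimen
regression slope (PI % per unit BMD) and Pearson r — is the quantity of
interest for bone-strength and stress-injury research.

The package implements the full workflow:

- **`voxel_grid` / NIfTI I/O / `resample`** — 3D volumes with world
  geometry, lossless double-precision round trips, affine resampling.
- **`fit_calibration` / `apply_calibration`** — grey→BMD from phantom rods.
- **`compute_pi`** — the echo ratio with a background-floor validity mask.
- **`segment_bone`** — median filter (spherical kernel 2), Bernsen
  contrast-based local threshold, largest 26-connected component, and a
  parametric distal cut replacing interactive diaphysis removal.
- **`register_affine` / `align_pi_to_ct`** — multi-resolution affine
  registration by mutual information (partial-volume joint histogram,
  rigid-first coordinate descent), then PI resampled to the CT grid.
- **`regress_specimen` / `build_study_table`** — voxel-wise OLS of PI on
  BMD per specimen; study-level group summaries, Jarque–Bera normality
  checks and t-tests (forelimb vs hindlimb, left vs right, LF vs RF,
  LH vs RH).
- **`phantom_spec` / `simulate_specimen` / `study_plan` / `generate_study`**
  — a synthetic condyle generator (ellipsoid cap + shaft, cortical shell,
  spatial porosity field, two-pool MR signal, calibration rods, known
  CT–MR misalignment) providing ground truth for every stage.
- **`table1()` / `reproduce_table1()`** — the published per-limb
  slope/SE/r table of the six-horse cadaver study, and its summary
  statistics recomputed from it.

Results are tibbles with `tidy()`/`glance()` methods and
`autoplot()`/`plot_bmd_pi()`/`plot_slice()` graphics.

## Worked example

Reproduce the published study summary from the packaged per-limb table:

```r
library(porindex)
reproduce_table1()
#> <pi_study> 24 specimens (23 analyzable, 1 excluded)
#>   r    : mean -0.29 (range -0.43 to -0.14; SD 0.071, SE 0.015)
#>   slope: mean -0.0083 (range -0.012 to -0.0048; SD 0.0018, SE 0.00037)
#>   group mean r: forelimb -0.26, hindlimb -0.32, left -0.28, right -0.30, LF -0.26, RF -0.26, LH -0.29, RH -0.34
#>   fore_vs_hind: t = 2.118 (df 21), p = 0.046 [student]
#>   left_vs_right: t = 0.897 (df 21), p = 0.380 [student]
#>   LF_vs_RF: t = 0.106 (df 9), p = 0.918 [student]
#>   LH_vs_RH: t = 1.278 (df 10), p = 0.230 [student]
```

The mean r of −0.29 is a weak inverse BMD–PI correlation across the 23
analyzable limbs; only the forelimb/hindlimb contrast is significant at
the 0.05 level.

Run the full pipeline on one synthetic specimen with known ground truth:

```r
b   <- simulate_specimen(phantom_spec(), seed = 7)
out <- run_specimen(b, analysis_params(transform = "truth"),
                    horse = 1, limb = "LF")
out$regression
#> <pi_regression> horse 1 LF n = 66631 voxels
#>   PI = 143.4 + -0.1165 * BMD   (SE 0.000135)
#>   r = -0.958 (very strong), p = 0
b$truth$true_r
#> [1] -0.9917
plot_bmd_pi(out$scatter, out$regression)
```

The estimated voxel-wise r (−0.958) recovers the generator's ground truth
(−0.992) up to the attenuation caused by measuring PI at the coarser MR
resolution. `run_study(study_plan(), analysis_params())` does the same for
a six-horse, 24-limb study (one limb excluded, as in the cadaver study)
and returns the per-limb table with group comparisons.

A thin command-line wrapper is installed at
`system.file("cli", "porindex", package = "porindex")` with subcommands
`simulate`, `run-study` and `reproduce-table1`.

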