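---
title: "Cross-modality validation of apparent bone volume fraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality validation of apparent bone volume fraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Trabecular bone volume fraction (BV/TV) — the volume of bony struts per unit
volume of the examined region — is a structural marker of peri-articular bone
remodeling in osteoarthritis. The gold standard is micro-computed tomography
(microCT) at micrometre resolution, where individual trabeculae are resolved
and bone is bright. Clinical-resolution MR sequences invert both properties:
bone gives essentially no signal (dark), and voxels (here ~0.23 × 0.23 × 1 mm)
are larger than single trabeculae, so every voxel mixes bone and marrow
signal. An MR-derived *apparent* BV/TV is therefore resolution- and
threshold-dependent, and must be validated against microCT before it can
stand in for it.

This package implements the full validation chain:

1. a synthetic phantom generator standing in for cadaveric specimens,
2. the MR apparent-BV/TV measurement (cortical threshold calibration,
   standardized ROI stack, pixel counting),
3. the microCT measurement (global binarization, VOI extraction, mesh-based
   volume estimation),
4. the agreement statistics (Spearman correlation with Fisher-z intervals,
   Bland-Altman, ICC(3,1), RMS %CV, Fisher-z sample-size design),

together with a bundled ten-knee cadaveric dataset of paired measurements on
which the statistics are reproduced exactly.

## The phantom: what it emulates, and what it does not

`generate_microstructure()` draws white Gaussian noise on a fine isotropic
grid, smooths it with a separable Gaussian kernel, and keeps the top
`target_bvtv` quantile of voxels as bone. Quantile thresholding pins the
realized bone fraction to the target within one voxel, which is what makes
the phantom useful as ground truth: every downstream estimate has an exact
reference. The kernel standard deviation is `trabecular_scale / 2`, so the
field's autocorrelation falls to 1/e at `trabecular_scale` (default 0.3 mm, a
conventional trabecular spacing). A pure-bone cortical plate of configurable
thickness (default 0.4 mm) models the subchondral plate.

The default geometry is deliberately desk-scale: a 4 × 10 × 10 mm volume at
0.05 mm isotropic spacing (~3.5 million voxels). A real 9 μm acquisition of
the same volume would exceed 10^9 voxels; the scaled grid preserves the
qualitative resolution ordering (fine grid ≪ MR voxel, trabecular scale a
few fine voxels) while keeping a full ten-specimen cohort computable in
seconds per phantom. `fine_spacing` is a plain knob for users who want finer
grids.

Two renderers share the truth volume:

* `render_microct()` — bone ~180, marrow ~40 on an 8-bit scale, additive
  Gaussian noise (σ = 5), rounded and clipped to [0, 255]. With these
  defaults both classes sit ~20σ from the binarization threshold of 80, so
  segmentation is essentially exact — by design: the microCT arm is the gold
  standard, and its errors should be dominated by geometry (meshing,
  VOI quantization), not by intensity noise.
* `render_mr()` — the partial-volume forward model. Each MR voxel's bone
  fraction `f` is the exact block average of the truth; the noiseless signal
  is `f·bone_signal + (1−f)·marrow_signal` (defaults 20 and 200, bone dark);
  Rician noise is applied as `|(s + g₁σ) + i g₂σ|` with independent standard
  normal `g₁, g₂` and σ = 10, the standard magnitude-image noise model.
  Optional axis-aligned lesion boxes multiply the local marrow signal before
  mixing, emulating hyperintense bone marrow lesions.

The default MR grid is 0.25 mm in-plane / 1 mm through-plane rather than the
protocol's 0.23 mm: MR voxels must tile the fine grid in integer blocks, and
0.25 = 5 × 0.05 mm preserves the in-plane : through-plane anisotropy that
drives partial-volume behaviour.

What the phantom does **not** model: anisotropic rod/plate trabecular
architecture, steady-state-precession signal physics, coil profiles,
chemical shift, beam hardening, ring artifacts, or cone-beam reconstruction.
Passing tests therefore demonstrate that the *measurement and statistics
chain* is correct under a controlled microstructure with known truth — not
that any particular scanner reproduces these numbers on tissue.

### The superior margin

A design point that deserves its own paragraph. If the phantom's cortical
plate starts exactly at the volume face, its boundaries coincide with MR
voxel boundaries and one MR row is *pure* bone. That row alone contributes a
constant ≈3.5% floor to apparent BV/TV — and real data contradict it: with
the plate inside the ROI, measured cadaveric apparent BV/TV reaches down to
0.09%, which is only possible if plate pixels are partial-volume mixed above
the threshold. Imaging grids are never aligned with anatomy. The generator
therefore inserts a `superior_margin` of signal-bearing tissue (default
0.3 mm, cartilage/marrow-like) above the plate, chosen so that neither plate
boundary falls on an MR row boundary at the default spacings. With the
margin, plate rows mix bone and soft-tissue signal exactly as partial volume
dictates, and the cohort-level ordering of apparent BV/TV against truth is
restored (Spearman ≈ 0.95 in the package's own end-to-end tests).

## MR morphometry

All ROI geometry is in physical millimetres. A pixel belongs to an ROI when
its *center* lies in the half-open rectangle `[top_left, top_left + (h, w))`;
voxel `i` has its center at `origin + (i − 1/2) · spacing`. Half-open
intervals make adjacent ROIs partition the grid without double counting, and
the center rule makes counts exact at integer size ratios
(a 0.69 mm ROI on a 0.23 mm grid is exactly 3 × 3 pixels).

The threshold calibration pools the pixel intensities of twenty
0.69 × 0.69 mm cortical-bone ROIs and takes their **pooled mean** as the
standardized threshold. The protocol this models does not specify how twenty
ROI intensities become one threshold; the pooled mean is the simplest
defensible reading, and `mean + k·SD` and percentile statistics are exposed
as options (`statistic =` in `calibrate_cortical_threshold()`). Because the
trabecular phantom contains no thick cortical bone (the anatomical
calibration site is the femoral shaft cortex, outside the modeled volume),
`synthetic_cortical_calibration()` renders an all-bone block with the same MR
settings and calibrates on that; for Rice(20, 10) noise the pooled-mean
threshold lands near 23.7.

`apparent_bvtv()` counts pixels with intensity **at or below** the threshold
(inclusive), divides by the ROI pixel count per slice, and averages the
per-slice fractions. With a constant ROI the per-slice mean and the pooled
pixel fraction coincide; the per-slice definition is kept because it is the
operational protocol. The standardized stack places the same rectangle on
the `n_slices` consecutive central slices, shifting toward the lower index
when the spare slice count is odd. The anchor (immediately below the
articular cartilage) is anatomical and must be supplied; automating it is
out of scope.

Two exact properties pin the implementation: with a noiseless rendering at
fine spacing and any threshold strictly between the bone and marrow signals,
apparent BV/TV equals the true voxel fraction exactly; and with the
plate-calibrated threshold on noiseless coarse renderings it can only
undercount (only `f = 1` voxels reach the threshold), reproducing the
conservative-threshold underestimation by construction.

## MicroCT morphometry

`binarize_global()` classifies bone as `lower ≤ I ≤ upper`, **both bounds
inclusive** (defaults 80 and 255 on the 8-bit scale). `extract_voi()` applies
the same center-in-half-open-box rule as the ROI code; the default VOI
reproduces the 3.939 × 13.729 × 17 mm peri-articular tibial box. In the
synthetic pipeline the VOI is placed below the margin + plate so that the
microCT reference measures the same trabecular compartment whose true
fraction is known; a config flag (`include_plate`) lets users probe the
MR/CT ROI mismatch instead.

`marching_cubes_bvtv()` estimates bone volume from a surface mesh: the mask
is padded with one background voxel per face, each grid cell is split into
six tetrahedra sharing the main diagonal (Kuhn decomposition, which matches
triangulations across cell faces), and the level-0.5 iso-surface of the
binary field is extracted with linear interpolation — the marching-
tetrahedra member of the marching-cubes family. This variant is used instead
of the classic 256-case cube tables because on binary fields it is
guaranteed watertight and orientation-consistent (no ambiguous cube cases),
and its enclosed volume has an exact characterization: it is precisely the
volume of the `{piecewise-linear interpolant ≥ 1/2}` superlevel set. The test
suite exploits that identity with an independent counting oracle (a
tetrahedron with `k` of 4 corners inside contributes 0, 1/8, 1/2, 7/8, 1 of
its volume). Enclosed volume is computed by the divergence theorem over the
outward-oriented triangles; total volume is voxel count × voxel volume of
the VOI (not the mesh bounding box), and `voxel_count_bvtv()` is the direct
oracle estimator.

A geometric subtlety worth knowing: on a full cuboid the mesh passes half a
voxel beyond the boundary voxel centers on each face, but bevels the cuboid's
edges and corners at 45°, so a 10³ all-bone block meshes to BV/TV ≈ 0.986,
not 1.0 — an O(1/n²) finite-resolution effect of *any* linear-interpolation
iso-surface (the classic cube tables give 0.9857 on the same input), which
vanishes under grid refinement. On smooth structures at the default
resolution the mesh and voxel-count estimates agree within 0.005; the test
suite enforces 0.02 across BV/TV levels and checks the discrepancy shrinks
when the grid is refined 2×.

## Agreement statistics

All statistics operate on tidy per-specimen tables
(`microct_bvtv_percent`, `mr_bvtv_percent`, optional `side`):

* **Spearman ρ** — Pearson correlation of mid-ranks (`stats::cor`,
  `method = "spearman"`); undefined for constant vectors, which error
  explicitly.
* **Fisher-z interval** — `tanh(atanh(ρ) ± z·SE)` with `SE = 1/√(n−3)`. The
  interval method is a reconstruction: applied to the bundled dataset's
  ρ = 0.830303 at n = 10 it reproduces the published (0.42, 0.96) exactly at
  two decimals, which is why it is the default; the Bonett–Wright
  `SE = √((1+ρ²/2)/(n−3))` variant is available via `method = "bonett"`.
* **Sample size** — `n = ⌈((z₁₋α/₂ + z_power)/(atanh ρ₁ − atanh ρ₀))² + 3⌉`;
  for ρ₁ = 0.80, α = 0.05, power 0.80 this gives exactly the ten knees of
  the study design.
* **Bland-Altman** — differences are **MR − microCT** throughout, so the
  conservative-threshold underestimation appears as a negative bias; limits
  are bias ± 1.96·SD with the n−1 divisor.
* **ICC(3,1)** — two-way mixed, single measurement, consistency:
  `(BMS − EMS)/(BMS + (k−1)·EMS)` from `stats::aov` mean squares; tests
  verify it against hand-computed sums of squares. Consistency ICC ignores
  fixed rater offsets, which is the point of using it for intra-rater
  reliability.
* **RMS %CV** — per duplicate pair `sd = |d|/√2` (n−1 divisor; an n-divisor
  flag exists), CV = sd/mean, result `100·√(mean CV²)`; scale-invariant by
  construction.

Each knee is treated as an independent observation, matching the primary
analysis being reproduced; no donor-level clustering correction is applied,
and that is a known limitation of both. Printed comparisons round half away
from zero (`round_half_up()`), since banker's rounding can differ in the
second decimal.

A note on the per-side coefficients: recomputing from the bundled table
yields ρ = 0.90 for the rows labeled right and ρ = 0.80 for left, while the
prose of the source study attaches 0.80 to right and 0.90 to left. The
package reports the coefficients with explicit side labels and validates
them as the unordered set {0.80, 0.90}.

## Numerical choices and degenerate inputs

* Quantile thresholding uses the exact k-th order statistic with ties broken
  by voxel index, so `target_bvtv` of 0 and 1 produce empty/full trabecular
  regions and every target is hit within one voxel.
* `render_mr()` crops the fine grid (from the high-index side) to the
  largest subgrid tiled exactly by MR voxels; spacing ratios must be integer
  within 1%.
* An empty mask yields BV/TV 0 with a warning from the mesh estimator, not
  an error; a negative enclosed volume (impossible for a consistent mesh)
  errors.
* All randomness flows through explicit integer seeds; per-stage seeds are
  derived deterministically from the specimen seed, and `withr::with_seed`
  restores the caller's RNG state. Identical spec + seed is bit-identical
  output.
* ROI/VOI boundary arithmetic carries a 10⁻⁹ epsilon so exact mm/spacing
  ratios (0.69/0.23, 17/0.05) are not broken by floating-point
  representation.

## Problem sizes used by the test suite

Module tests use 2.4–3.2 mm phantoms (≈50³–64³ voxels). The end-to-end
acceptance checks use the default 10 × 10 × 4 mm cohort geometry: ten
phantoms per cohort and twenty replicate cohorts for the
direction-of-bias property, ten seeds for microCT recovery, and two grid
resolutions (0.1/0.05 mm) for the refinement property. These sizes were
chosen so the full suite runs in a few minutes on a single core while every
Monte-Carlo claim still spans ≥ 10 independent replicates.

## Known limitations

* The Gaussian-random-field microstructure is isotropic; real trabecular
  bone is anisotropic and plate-like, so the phantom's partial-volume tail
  (the share of nearly-pure-bone MR voxels) is conservative relative to
  tissue.
* The phantom has no quantitative microstructural statistics (trabecular
  thickness/number/spacing) fitted to any specimen set; `trabecular_scale`
  is conventional.
* TIFF export does not carry voxel spacing; it must be supplied on read (the
  run manifest records it).
* The ICC(3,1) and RMS %CV implementations are validated against synthetic
  duplicates; the reliability figures of the source protocol rest on
  unpublished re-read data and are not reproduced here.
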