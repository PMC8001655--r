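---
title: "Methods: digital volume correlation and differential tomography for bone microcracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital volume correlation and differential tomography for bone microcracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`dvctomo`. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The processing model

A time-lapse micro-CT experiment on a loaded cortical-bone sample produces,
per load state, a projection series and (after reconstruction, which is out
of scope here) a 3D grayscale volume. The package implements the
post-processing chain around the reconstruction:

1. **Projection preparation** — flat-field correction
   `(raw − dark) / (open − dark)` with bad-pixel replacement, and focal-spot
   drift compensation from interleaved reference exposures.
2. **DVC** — two-step sub-volume tracking between the reference and loaded
   volumes: integer-voxel search maximizing zero-mean (Pearson) NCC over
   cubic windows, then sub-voxel Gauss–Newton refinement under a local
   12-parameter affine warp (3D Lucas–Kanade).
3. **Local registration and blending** — a 5×5×5 cube of 125 DVC support
   points near (but standing off from) a crack tip feeds a weighted
   least-squares transformation fit (general affine or orthogonal
   Procrustes rigid); the loaded volume is resampled and blended,
   `Vb = Vr + m·Vl`, exposing newly formed voids at high contrast.
4. **Strain mapping** — per-cell least-squares affines of the nodal
   displacement lattice give deformation gradients `F` and Green–Lagrange
   tensors `E = (FᵀF − I)/2`.
5. **Crack metrology** — FWHM of line intensity profiles, and mask-based
   width/length from the Euclidean distance transform and geodesic
   diameter.

### Assumptions

* Intensity is conserved between states up to the tracked geometric
  transformation (no contrast change between scans).
* Deformation is locally affine at the correlation-window scale
  (window 18 voxels ≈ 36 µm at 2 µm voxels).
* Focal-spot drift is slow: linear in acquisition index within a sub-scan.
* Cracks are voids: intensity dips to the air/void level.

## 2. Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window_size` | 18 | voxels | correlation-window edge; even, ≥ 6. 18 is the calibration optimum; smaller windows lose convergence and accuracy, larger cost more. |
| `node_offset` | 24 | voxels | node-grid spacing on the evaluated plane. |
| `prefilter_kernel` | 13 | voxels | 3D median prefilter edge (odd); suppresses reconstruction noise before correlation. Use 1 (off) on noise-free synthetic data. |
| `search_radius` | 10 | voxels | integer-search bound per axis around the initial guess. |
| `max_iterations` / `tolerance` | 50 / 1e-3 | – / voxels | Gauss–Newton cap and update-norm convergence threshold. |
| blending `m` | 20 | – | integer multiplier of `Vb = Vr + m·Vl`; searched over 2..50 by contrast-to-noise. |
| `min_ncc` (registration) | 0.9 | – | support points below this correlation are excluded from the transform fit. |
| `exclusion_margin` (segmentation) | 50 | µm | surface-shell thickness; void components touching it (air, through-canals, preparation damage) are discarded. |
| FWHM baseline | outer 20% | – | baseline = median of the outer 10% of samples at each profile end. |

## 3. The synthetic phantom: what it emulates, what it does not

`make_bone_phantom()` generates the validation world: a cylindrical tissue
region (axis z, diameter 90% of the cross-section) at `tissue_level` (200)
against air/void at `void_level` (20), multiplicative speckle texture
(smoothed Gaussian field, σ = 1.5 voxels ⇒ ≈ 3-voxel correlation length,
amplitude 15% of tissue level), `canal_count` axial Haversian-canal
cylinders, optional additive Gaussian noise, and — through companion
generators — planar elliptical cracks of prescribed opening (half-open
distance band, so a k-voxel-wide axis-aligned crack occupies exactly k
voxel layers), affine/displacement-field deformations (trilinear
resampling), and parallel-beam projection series with a linear focal-spot
drift and per-sub-scan reference exposures. Every generator is a pure
function of its spec and seed and emits its ground truth.

It deliberately does **not** emulate: polychromatic attenuation and beam
hardening, scatter, detector PSF and afterglow, ring artifacts, cone-beam
geometry (projections are parallel-beam — drift correction operates on 2D
frame shifts either way), osteon-scale lamellar structure, or partial
mineralization gradients. A green test therefore establishes algorithmic
correctness against known geometry and the stated noise model — not
robustness to reconstruction artifacts of a physical scanner.

Default intensity levels (200/20) and texture amplitude (0.15) give the
void/tissue contrast and speckle visibility typical of reconstructed
cortical bone at ~2 µm voxels; noise defaults to zero because the
calibration experiments are defined on noise-free numerically shifted data.

## 4. Numerical choices

**Inverse-compositional Lucas–Kanade.** The sub-voxel refinement warps the
*pristine reference volume* onto the deformed-state window and inverts the
fitted affine, rather than sampling the deformed volume under a forward
warp. Both directions are standard in the Lucas–Kanade family; the inverse
form is preferred here because the deformed volume is typically itself an
interpolated image (resampled after registration, or synthesized by the
phantom), and sampling an already-interpolated image introduces a
systematic fractional-shift bias (measured at up to ~0.17 voxel on
translations and ~15–19% on a 0.02 shear with the forward form, versus
machine precision with the inverse form on interpolation-consistent data).
The same reasoning applies to the 2D drift DIC, which refines the
reference-frame match by warping the first (pristine) reference exposure.

**Line search.** Gauss–Newton on a piecewise-trilinear interpolant
limit-cycles near the optimum (the gradient is discontinuous across voxel
cells). Both refinements therefore backtrack on the SSD and declare
convergence at a stationary point where no improving step exists.

**Integer search.** Pure 26-neighbor hill climbing stalls on spurious
local maxima of the smooth-texture NCC surface. The search climbs
coarse-to-fine (strides halving from ~`search_radius` to 1) and, if the
final NCC is below 0.9, rescans the bounded cube at stride 2 and
re-climbs. An exhaustive scan remains available (`exhaustive = TRUE`) and
is the independent oracle in the tests.

**Drift estimation.** Reference frames are matched with a fixed interior
template (margin ≥ search radius): full-frame overlap correlation is
contaminated by the fill values that frame shifts drag in at the borders.
The integer NCC peak is seeded sub-pixel by a 2D log-Gaussian quadratic fit
on the 3×3 neighborhood (separate 1D fits fail on diagonally oriented
ridges) and polished by translation-only Lucas–Kanade. The first reference
defines the zero-drift datum; sub-scan endpoints are consecutive reference
shifts, the last sub-scan extrapolating its own trend; per-frame shifts
interpolate linearly over acquisition index.

**Field filtering.** Step 1 replaces unconverged nodes by the
component-wise median of converged lattice neighbors; step 2 applies a
median/MAD outlier rule (`k = 3`) with an absolute floor of 0.05 voxels —
without the floor, near-zero MADs in smooth converged fields flag ordinary
nodes and break idempotence.

**Calibration statistics.** σ_YZ is the standard deviation of the
deviation from the ideal in-plane magnitude pooled over *all* virtual load
steps; mean u_YZ, MBE and RMSE are evaluated at the final step. The volume
is median-prefiltered once and the shifted copies are derived from the
filtered volume (integer shifting commutes with the median filter away
from borders). Nodes that fail any step are excluded from the statistics
and counted as unconverged.

**Metrology definitions.** Crack width = `2·max(EDT) − voxel_size`: the
−1-voxel correction makes the formula exact for odd-layer axis-aligned
slabs and gives the single-voxel degenerate case one voxel of width
(plain `2·max(EDT)` overestimates every case by one voxel; even-layer
slabs remain one voxel under, i.e. within the stated ±1 voxel). Crack
length = geodesic diameter of the mask via double-sweep Dijkstra with a
5×5×5 neighborhood (chamfer error ≈ 1–2%); for the 1–3-voxel-thick masks
measured here the mask is its own medial surface, so no explicit
skeletonization is performed.

**Degenerate inputs.** Zero-variance windows are an error in
`integer_search` and an unconverged status in batch tracking; singular
normal matrices and non-invertible local affines are unconverged statuses;
resampling and deformation fill out-of-domain voxels with the air level;
a perfect integer frame match (NCC = 1) skips sub-pixel refinement.

## 5. Design decisions taken where the method was open

* **NCC form**: zero-mean, unit-variance (Pearson) — robust to intensity
  offset between scans.
* **General vs rigid registration**: both are implemented
  (`kind = "general"`/`"rigid"`); the general affine is the default, and
  the two agree to machine precision on noise-free rigid motion.
* **Support-point geometry**: the 125 points form a 5×5×5 cube with
  2-voxel spacing offset from the crack tip along a user-given outward
  direction; any overlap with a supplied void mask is an error. Local
  alignment accuracy should be judged at the support centroid — the
  affine's translation component alone extrapolates linear-part noise to
  the coordinate origin.
* **Blending multiplier selection**: the visual contrast inspection is made
  computable as the contrast-to-noise ratio
  `|mean_tissue − mean_void| / pooled SD` between user-sampled
  populations, maximized over the integer range.
* **Sub-scan shift**: the plan builder takes the angular shift between
  sub-scans as a parameter (default: the value that makes the merged set
  equiangular, 360°/(n·m)) and reports whether the merged angle set is
  uniform rather than assuming it.
* **Drift interpolation**: within a sub-scan the generator and the
  estimator both interpolate linearly over acquisition index, with the
  sub-scan's last projection sitting exactly at its end shift; for a
  globally linear drift the two models coincide exactly.

## 6. Known limitations

* Trilinear interpolation bounds sub-voxel accuracy on *real* (non
  interpolation-consistent) data; cubic-spline sampling would reduce the
  residual bias at higher cost.
* Double resampling (align + blend) smooths speckle texture; on the
  phantom the round-trip RMS error floor is ≈ 1.3% of dynamic range over
  interior tissue and several times that at material interfaces. Scores of
  the end-to-end crack detection therefore exclude one-voxel
  partial-volume interface layers and volume-border slices lost to the
  rigid motion.
* The outlier filter is local and cannot distinguish a genuine sharp
  displacement discontinuity (an opening crack face) from an outlier at
  the node spacing used here.
* Segmentation merges cracks with any void they touch (e.g. a canal a
  crack originates from); measurement then quantifies the merged object
  unless the caller separates them.
* The geodesic length of very thick or highly folded masks would need true
  skeletonization; the implemented diameter is accurate for thin, gently
  curved cracks.
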