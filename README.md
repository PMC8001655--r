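# dvctomo

Laboratory micro-CT post-processing for fatigue **microcrack detection in
cortical bone**: projection-level corrections with focal-spot drift
compensation, a two-step **digital volume correlation (DVC)** engine,
**differential tomography** by volume blending, **Green–Lagrange strain**
mapping, and **FWHM crack metrology** — validated end to end on a synthetic
bone phantom with exact ground truth, so no scan data is required.

## The problem

Time-lapse micro-CT of a loaded bone sample can reveal fatigue microcracks
only a few micrometres wide, but three obstacles stand between the raw
projections and a usable crack map:

1. **Focal-spot drift.** Long scans (~75 min) suffer slow thermo-mechanical
   source drift that translates every projection and blurs the
   reconstruction. The scan is split into interleaved sub-scans, each opened
   by a reference exposure at a fixed angle; correlating the reference
   series yields the drift, and every projection is shifted back by the
   linearly interpolated offset.
2. **Volume alignment.** Cyclic loading moves the sample by tens of voxels.
   A crack only becomes visible when the loaded-state volume `Vl` is
   precisely registered onto the reference `Vr` and the two are *blended*:

   `Vb = Vr + m · Vl`,  `m ∈ [2, 50]` (optimum `m = 20`),

   which renders newly formed voids at high contrast against tissue.
3. **Displacement and strain.** Sub-volume tracking (DVC) recovers the
   displacement field: an integer-voxel search maximizing zero-mean
   normalized cross-correlation (NCC) over cubic windows, followed by a 3D
   Lucas–Kanade refinement under a 12-parameter local affine warp. Nodal
   displacements give per-cell deformation gradients `F` and the
   Green–Lagrange tensor `E = (FᵀF − I)/2`.

The correlation window size is chosen by a *virtual experiment*: the volume
is rigidly shifted in five numerical steps of 4 voxels along both in-plane
axes (ideal displacement magnitude `√(20² + 20²) = 28.2842 px`) and the
recovery error (σ, mean-bias error, RMSE) is tabulated per window size.

## Worked example

```r
library(dvctomo)

# a synthetic cortical-bone sample: cylinder + speckle texture (canal-free
# here so the inserted crack is the only internal void)
ph  <- make_bone_phantom(phantom_spec(shape = c(64, 64, 64), voxel_size = 2,
                                      canal_count = 0, seed = 1))

# loaded state: rigid sub-voxel motion plus a new penny-shaped crack
move   <- affine_transform(diag(3), c(0.8, -0.5, 0.3))
loaded <- apply_deformation(ph$volume, move)
ins    <- insert_crack(volume(loaded$data, voxel_size = 2),
                       crack_spec(center = c(32, 32, 32), normal = c(1, 0, 0),
                                  half_extent = 22, width = 10),
                       void_level = 20, tissue_mask = ph$tissue_mask)

# local alignment from 125 DVC support points near the crack tip
reg <- register_local(ph$volume, ins$volume, crack_tip = c(32, 32, 43),
                      standoff = 10, direction = c(0, 0, 1), min_ncc = 0.98,
                      cfg = correlation_config(window_size = 12,
                                               prefilter_kernel = 1,
                                               search_radius = 4))
round(reg$transform$translation, 4)
#> [1]  0.8 -0.5  0.3          # the prescribed rigid move, recovered

# differential tomography: blend, segment, measure
vb   <- blend(ph$volume, resample_volume(ins$volume, reg$transform), m = 20)
mask <- largest_component(segment_voids(vb, threshold = "otsu",
                                        exclusion_margin = 10))
measure_crack(mask, voxel_size = 2)
#> crack: width 10 um, length 45.6 um (1865 voxels, mask-based)
```

The measured width equals the inserted 10 µm opening, and the length
matches the ground-truth mask measured the same way (45.89 µm for the
44 µm-diameter penny crack — the geodesic diameter picks up the rim
thickness).

Window-size calibration (the virtual rigid-motion experiment, here with
five 2-voxel steps on the 64³ demo phantom):

```r
calibrate_window(ph, window_sizes = c(6, 12, 18), n_steps = 5,
                 step_shift = c(2, 2, 0),
                 region = list(z = 20:39, y = 20:39, x = 32),
                 cfg = correlation_config(prefilter_kernel = 3,
                                          search_radius = 5))
#>   window_size elapsed_s unconverged mean_uYZ sigma_YZ    mbe  rmse
#> 1           6     0.472           2    13.99   0.9582 0.1569 1.183
#> 2          12     1.844           0    14.14   0.0000 0.0000 0.000
#> 3          18     6.123           0    14.14   0.0000 0.0000 0.000
```

Small windows lose nodes and carry recovery error; from 12 voxels up every
node converges on the ideal `sqrt(10² + 10²) = 14.14 px` — the same
behavior the full-scale calibration shows at 28.28 px for the prescribed
20 + 20-voxel motion.

## Command line

```sh
exec/dvct phantom --out ph.raw --shape 64,64,64 --seed 7
exec/dvct calibrate --volume ph.raw --windows 6,12,18 --out table.csv
exec/dvct blend --ref ref.tif --def loaded.tif --m 20 --out blended.tif
exec/dvct measure --mask crack.raw --out crack.json
```

Sub-commands: `phantom`, `drift-correct`, `correlate`, `calibrate`,
`register`, `blend`, `strain`, `measure`. All options can also come from a
JSON file via `--config`; unknown keys are rejected and each run logs its
resolved configuration.

## Documentation

The methods vignette (`vignettes/dvctomo-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults, what
the phantom does and does not emulate, and the numerical choices
(inverse-compositional Lucas–Kanade, line search, strided NCC search,
metrology definitions).
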