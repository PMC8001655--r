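# Synthetic bone phantom with exact ground truth.
#
# The generator emulates the imaged specimen class: a cylindrical cortical
# bone sample with axial Haversian canals acting as stress concentrators,
# multiplicative speckle texture (the natural bone texture DVC relies on),
# thin planar microcracks at void intensity, prescribed rigid/affine
# deformations, and parallel-beam projection series with a slow linear
# focal-spot drift. Every generator is a pure function of its spec and seed
# and emits its ground truth (masks, shifts, transforms) alongside the data.

#' Specify a synthetic bone phantom
#'
#' @param shape grid dimensions `(nz, ny, nx)`.
#' @param voxel_size voxel edge, micrometres (scalar or length 3).
#' @param canal_count number of axial Haversian-canal cylinders.
#' @param canal_radius canal radius, micrometres (>= 1 voxel).
#' @param texture_amplitude multiplicative speckle amplitude as a fraction of
#'   tissue intensity (correlation length about 3 voxels).
#' @param tissue_level,void_level mean intensities of mineralized tissue and
#'   void/air; `void_level < tissue_level`.
#' @param noise_sigma additive Gaussian noise scale (0 = noise-free).
#' @param seed RNG seed; identical seed gives a bit-identical phantom.
#' @return a `dvct_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = 2,
                         canal_count = 3, canal_radius = 8,
                         texture_amplitude = 0.15, tissue_level = 200,
                         void_level = 20, noise_sigma = 0, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stopf("shape must be three positive integers (nz, ny, nx)")
  }
  voxel_size <- as_len3(voxel_size, "voxel_size")
  if (void_level >= tissue_level) stopf("void_level must be < tissue_level")
  if (canal_count > 0L && canal_radius < min(voxel_size)) {
    stopf("canal_radius must be at least one voxel")
  }
  structure(list(shape = shape, voxel_size = voxel_size,
                 canal_count = as.integer(canal_count),
                 canal_radius = canal_radius,
                 texture_amplitude = texture_amplitude,
                 tissue_level = tissue_level, void_level = void_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "dvct_phantom_spec")
}

# in-plane squared distance grid (ny x nx) from a (y, x) center in um
plane_dist2 <- function(ny, nx, cy, cx, vs) {
  dy <- ((seq_len(ny) - 1) * vs[2] - cy)
  dx <- ((seq_len(nx) - 1) * vs[3] - cx)
  outer(dy^2, dx^2, `+`)
}

#' Generate a synthetic cortical-bone phantom
#'
#' A cylindrical tissue region (axis along z) at `tissue_level` modulated by
#' smoothed multiplicative speckle, `canal_count` axial canal cylinders at
#' `void_level`, air at `void_level` outside the sample, and optional
#' additive Gaussian noise. Canal positions are drawn inside 70% of the
#' sample radius; placement that cannot keep a canal fully inside the
#' cylinder is an error.
#'
#' @param spec a [phantom_spec()].
#' @return a `dvct_phantom` list: `volume` (a [volume()]), logical ground
#'   truth arrays `cylinder_mask`, `canal_mask`, `tissue_mask`
#'   (cylinder minus canals), and `spec`.
#' @export
make_bone_phantom <- function(spec) {
  if (!inherits(spec, "dvct_phantom_spec")) {
    stopf("spec must come from phantom_spec()")
  }
  d <- spec$shape
  vs <- spec$voxel_size
  cy <- (d[2] - 1) / 2 * vs[2]
  cx <- (d[3] - 1) / 2 * vs[3]
  radius <- 0.45 * min((d[2] - 1) * vs[2], (d[3] - 1) * vs[3])
  if (spec$canal_count > 0L && spec$canal_radius >= 0.7 * radius) {
    stopf("canal_radius %.3g um cannot fit inside the %.3g um sample radius",
          spec$canal_radius, radius)
  }
  d2 <- plane_dist2(d[2], d[3], cy, cx, vs)
  cyl2d <- d2 <= radius^2
  with_seed(spec$seed, {
    canal2d <- matrix(FALSE, d[2], d[3])
    if (spec$canal_count > 0L) {
      max_r <- 0.7 * radius
      placed <- 0L
      centers <- matrix(0, 0, 2)
      attempts <- 0L
      while (placed < spec$canal_count) {
        attempts <- attempts + 1L
        if (attempts > 1000L) {
          stopf("could not place %d canals inside the cylinder",
                spec$canal_count)
        }
        rr <- sqrt(runif(1)) * max_r
        th <- runif(1) * 2 * pi
        cand <- c(cy + rr * sin(th), cx + rr * cos(th))
        if (rr + spec$canal_radius >= radius) next
        # keep canals separated so component counts match canal_count
        if (placed > 0L) {
          sep <- sqrt((centers[, 1] - cand[1])^2 +
                        (centers[, 2] - cand[2])^2)
          if (any(sep < 2.5 * spec$canal_radius)) next
        }
        centers <- rbind(centers, cand)
        canal2d <- canal2d |
          (plane_dist2(d[2], d[3], cand[1], cand[2], vs) <=
             spec$canal_radius^2)
        placed <- placed + 1L
      }
    }
    vol <- array(spec$void_level, d)
    cyl3d <- aperm(array(cyl2d, c(d[2], d[3], d[1])), c(3, 1, 2))
    canal3d <- aperm(array(canal2d, c(d[2], d[3], d[1])), c(3, 1, 2))
    tissue <- cyl3d & !canal3d
    tis_val <- rep(spec$tissue_level, sum(tissue))
    if (spec$texture_amplitude > 0) {
      # smoothed random field; sigma 1.5 gives the ~3-voxel correlation
      # length the speckle texture is meant to have
      field <- array(rnorm(prod(d)), d)
      field <- cpp_gaussian_smooth3(field, 1.5)
      field <- field / stats::sd(field)
      tis_val <- spec$tissue_level *
        (1 + spec$texture_amplitude * field[tissue])
    }
    vol[tissue] <- tis_val
    if (spec$noise_sigma > 0) {
      vol <- vol + array(rnorm(prod(d), sd = spec$noise_sigma), d)
    }
    structure(list(volume = volume(vol, voxel_size = vs),
                   cylinder_mask = cyl3d, canal_mask = canal3d,
                   tissue_mask = tissue, spec = spec),
              class = "dvct_phantom")
  })
}

#' @export
print.dvct_phantom <- function(x, ...) {
  cat(sprintf("dvct_phantom: %s voxels, %d canal(s), seed %d\n",
              paste(x$spec$shape, collapse = " x "), x$spec$canal_count,
              x$spec$seed))
  invisible(x)
}

#' Specify a planar microcrack
#'
#' @param center crack center, 1-based voxel coordinates `(z, y, x)`.
#' @param normal crack-plane normal (any nonzero 3-vector, normalized
#'   internally).
#' @param half_extent in-plane half-lengths in micrometres (scalar for a
#'   penny crack, length 2 for an elliptical one).
#' @param width crack opening in micrometres (>= 1 voxel equivalent).
#' @param waviness amplitude (micrometres) of a low-frequency sinusoidal
#'   perturbation of the crack surface; 0 for a flat plane.
#' @return a `dvct_crack_spec` list.
#' @export
crack_spec <- function(center, normal = c(0, 0, 1), half_extent, width,
                       waviness = 0) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || sum(normal^2) == 0) {
    stopf("normal must be a nonzero 3-vector")
  }
  half_extent <- as.numeric(half_extent)
  if (length(half_extent) == 1L) half_extent <- rep(half_extent, 2L)
  structure(list(center = as.numeric(center),
                 normal = normal / sqrt(sum(normal^2)),
                 half_extent = half_extent, width = width,
                 waviness = waviness),
            class = "dvct_crack_spec")
}

# orthonormal in-plane basis completing `n` to a right-handed frame
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  rbind(e1, e2)
}

#' Insert a planar microcrack into a volume
#'
#' Voxels whose signed distance `s` to the (optionally wavy) crack plane
#' satisfies `-width/2 <= s < width/2` and whose in-plane position lies
#' inside the elliptical extent are set to `void_level`. The half-open
#' distance band makes an axis-aligned crack of width `k` voxels occupy
#' exactly `k` voxel layers. The ground-truth mask is returned with the
#' volume.
#'
#' @param v a [volume()] or a `dvct_phantom` (whose tissue mask then bounds
#'   the crack).
#' @param crack a [crack_spec()].
#' @param void_level intensity assigned to crack voxels; defaults to the
#'   phantom's void level or `min(v$data)`.
#' @param tissue_mask optional logical array restricting the crack.
#' @return list with `volume` (modified) and logical `mask`.
#' @export
insert_crack <- function(v, crack, void_level = NULL, tissue_mask = NULL) {
  if (!inherits(crack, "dvct_crack_spec")) {
    stopf("crack must come from crack_spec()")
  }
  if (inherits(v, "dvct_phantom")) {
    if (is.null(void_level)) void_level <- v$spec$void_level
    if (is.null(tissue_mask)) tissue_mask <- v$tissue_mask
    v <- v$volume
  }
  check_volume(v)
  if (is.null(void_level)) void_level <- min(v$data)
  d <- dim(v$data)
  vs <- v$voxel_size
  n <- crack$normal
  eb <- plane_basis(n)
  cen <- (crack$center - 1) * vs  # physical um
  # physical coordinates of every voxel center
  zc <- (seq_len(d[1]) - 1) * vs[1]
  yc <- (seq_len(d[2]) - 1) * vs[2]
  xc <- (seq_len(d[3]) - 1) * vs[3]
  pz <- array(zc, d) - cen[1]
  py <- aperm(array(yc, c(d[2], d[1], d[3])), c(2, 1, 3)) - cen[2]
  px <- aperm(array(xc, c(d[3], d[1], d[2])), c(2, 3, 1)) - cen[3]
  s <- pz * n[1] + py * n[2] + px * n[3]
  r1 <- pz * eb[1, 1] + py * eb[1, 2] + px * eb[1, 3]
  r2 <- pz * eb[2, 1] + py * eb[2, 2] + px * eb[2, 3]
  if (crack$waviness != 0) {
    s <- s - crack$waviness * sin(pi * r1 / max(crack$half_extent[1], 1e-9))
  }
  a <- crack$half_extent[1]
  b <- crack$half_extent[2]
  mask <- (s >= -crack$width / 2) & (s < crack$width / 2)
  mask <- mask & if (a > 0 && b > 0) {
    (r1 / a)^2 + (r2 / b)^2 <= 1
  } else {
    array(FALSE, d)
  }
  if (!is.null(tissue_mask)) {
    if (!any(mask & tissue_mask) && any(mask)) {
      stopf("crack lies entirely outside the tissue region")
    }
    mask <- mask & tissue_mask
  }
  out <- v
  out$data[mask] <- void_level
  list(volume = out, mask = mask)
}

#' Apply a prescribed deformation to a volume
#'
#' `transform` is either an [affine_transform()] describing the forward
#' motion of material points (reference -> deformed, 0-based voxel
#' coordinates) or a list of three displacement arrays `uz, uy, ux` (voxels,
#' on the output grid). Intensities are resampled at back-mapped coordinates
#' with trilinear interpolation; voxels mapping outside the domain are filled
#' with `fill` (air level).
#'
#' @param v a [volume()].
#' @param transform an [affine_transform()] or `list(uz =, uy =, ux =)`.
#' @param fill intensity for out-of-domain voxels; default `min(v$data)`.
#' @return the deformed [volume()].
#' @export
apply_deformation <- function(v, transform, fill = NULL) {
  check_volume(v)
  if (is.null(fill)) fill <- min(v$data)
  if (inherits(transform, "dvct_affine")) {
    if (!all(is.finite(transform$linear)) ||
        !all(is.finite(transform$translation))) {
      stopf("transform must be finite")
    }
    li <- tryCatch(solve(transform$linear), error = function(e) NULL)
    if (is.null(li)) stopf("non-invertible linear part")
    # deformed(x) = v(L^-1 (x - t))
    out <- cpp_resample_affine(v$data, li,
                               as.numeric(-li %*% transform$translation),
                               fill)
  } else if (is.list(transform) &&
             all(c("uz", "uy", "ux") %in% names(transform))) {
    if (!all(vapply(transform[c("uz", "uy", "ux")], function(u) {
      identical(dim(u), dim(v$data)) && all(is.finite(u))
    }, logical(1L)))) {
      stopf("displacement arrays must match the volume and be finite")
    }
    out <- cpp_warp_field(v$data, transform$uz, transform$uy, transform$ux,
                          fill)
  } else {
    stopf("transform must be an affine_transform or list(uz, uy, ux)")
  }
  volume(out, voxel_size = v$voxel_size, origin = v$origin)
}

#' Specify a focal-spot drift path
#'
#' Per-sub-scan detector-plane shift endpoints in pixels `(row, column)`.
#' Within a sub-scan the shift interpolates linearly between its endpoints
#' over the acquisition index.
#'
#' @param shift_at_start,shift_at_end `n_subscans x 2` matrices of `(row,
#'   col)` shifts in pixels.
#' @return a `dvct_drift_path`.
#' @seealso [linear_drift_path()] for the canonical slow linear drift.
#' @export
drift_path <- function(shift_at_start, shift_at_end) {
  shift_at_start <- rbind(shift_at_start)
  shift_at_end <- rbind(shift_at_end)
  if (!identical(dim(shift_at_start), dim(shift_at_end)) ||
      ncol(shift_at_start) != 2L) {
    stopf("shift endpoints must be n_subscans x 2 matrices")
  }
  if (!all(is.finite(shift_at_start)) || !all(is.finite(shift_at_end))) {
    stopf("drift shifts must be finite")
  }
  structure(list(shift_at_start = shift_at_start,
                 shift_at_end = shift_at_end,
                 n_subscans = nrow(shift_at_start)),
            class = "dvct_drift_path")
}

#' Build a globally linear drift path
#'
#' Models the slow thermo-mechanical focal-spot drift of a long scan: the
#' detector-plane shift grows linearly with acquisition index from `(0, 0)`
#' at the first reference exposure to `total_shift` at the last acquired
#' frame; per-sub-scan endpoints are the restriction of that line (sub-scan
#' `k` starts at global frame slot `(k - 1) * (n_per_subscan + 1)` and ends
#' `n_per_subscan` slots later).
#'
#' @param total_shift final `(row, col)` shift in pixels.
#' @param plan the [build_scan_plan()] the projections will follow.
#' @return a [drift_path()].
#' @export
linear_drift_path <- function(total_shift, plan) {
  check_scan_plan(plan)
  total_shift <- as.numeric(total_shift)
  npg <- plan$n_per_subscan + 1L
  total_slots <- plan$n_subscans * npg - 1L
  g0 <- (seq_len(plan$n_subscans) - 1L) * npg
  drift_path(outer(g0 / total_slots, total_shift),
             outer((g0 + plan$n_per_subscan) / total_slots, total_shift))
}

#' Generate a drifting projection series from a volume
#'
#' Parallel-beam line-integral projections (sum along rays after in-plane
#' rotation by each angle) acquired per the scan plan: each sub-scan starts
#' with a reference exposure at the plan's fixed reference angle followed by
#' its angular projections. Every frame is translated by the drift
#' interpolated at its acquisition index (sub-pixel via bilinear
#' resampling); the ground-truth per-frame shifts are returned.
#'
#' @param v a [volume()].
#' @param plan a [build_scan_plan()].
#' @param drift a [drift_path()] with `plan$n_subscans` sub-scans.
#' @param noise_sigma additive Gaussian detector noise (0 = none).
#' @param seed RNG seed for the noise.
#' @return list with `series` (a [projection_series()]) and `shifts`
#'   (`n_frames x 2` matrix of true `(row, col)` shifts).
#' @export
make_drifting_projections <- function(v, plan, drift, noise_sigma = 0,
                                      seed = 1) {
  check_volume(v)
  check_scan_plan(plan)
  if (!inherits(drift, "dvct_drift_path")) {
    stopf("drift must come from drift_path()")
  }
  if (drift$n_subscans != plan$n_subscans) {
    stopf("drift has %d sub-scans but plan has %d", drift$n_subscans,
          plan$n_subscans)
  }
  if (plan$n_subscans < 1L || plan$n_per_subscan < 1L) stopf("empty plan")
  ann <- scan_plan_annotation(plan)
  nfr <- length(ann$angles_deg)
  npg <- plan$n_per_subscan + 1L  # frames per sub-scan incl. reference
  shifts <- matrix(0, nfr, 2)
  frames <- vector("list", nfr)
  with_seed(seed, {
    for (f in seq_len(nfr)) {
      k <- ann$subscan_index[f]
      slot <- (f - 1L) %% npg  # 0 = reference exposure
      frac <- slot / plan$n_per_subscan  # last projection sits exactly at end
      sh <- drift$shift_at_start[k, ] +
        frac * (drift$shift_at_end[k, ] - drift$shift_at_start[k, ])
      p <- cpp_project_parallel(v$data, ann$angles_deg[f])
      p <- cpp_shift2d(p, sh[1], sh[2], 0)
      if (noise_sigma > 0) {
        p <- p + matrix(rnorm(length(p), sd = noise_sigma), nrow(p))
      }
      frames[[f]] <- p
      shifts[f, ] <- sh
    }
  })
  list(series = projection_series(frames, ann$angles_deg, ann$subscan_index,
                                  ann$is_reference),
       shifts = shifts)
}
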