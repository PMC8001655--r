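# Two-step digital volume correlation: integer-voxel NCC search (steepest
# gradient / 26-neighbor hill climb with exhaustive fallback) followed by a
# modified 3D Lucas-Kanade sub-voxel refinement under a 12-parameter local
# affine warp, plus the displacement-field filtering and the window-size
# calibration protocol based on virtual rigid-body motion.

#' Correlation configuration
#'
#' @param window_size cubic correlation-window edge in voxels; must be even
#'   and at least 6 (the range swept by the calibration protocol). Default 18,
#'   the optimum found by the window-size calibration.
#' @param node_offset node-grid spacing on the evaluated plane, voxels.
#' @param prefilter_kernel edge of the 3D median prefilter cube (odd);
#'   default 13. Use 1 to disable on noise-free data.
#' @param search_radius integer-search bound around the initial guess,
#'   voxels.
#' @param max_iterations cap on Gauss-Newton refinement iterations.
#' @param tolerance convergence threshold on the refinement update norm,
#'   voxels.
#' @return a `dvct_config` list.
#' @export
correlation_config <- function(window_size = 18, node_offset = 24,
                               prefilter_kernel = 13, search_radius = 10,
                               max_iterations = 50, tolerance = 1e-3) {
  window_size <- as.integer(window_size)
  if (window_size < 6L || window_size %% 2L != 0L) {
    stopf("window_size must be even and >= 6")
  }
  prefilter_kernel <- as.integer(prefilter_kernel)
  if (prefilter_kernel < 1L || prefilter_kernel %% 2L != 1L) {
    stopf("prefilter_kernel must be odd and >= 1")
  }
  if (tolerance <= 0) stopf("tolerance must be > 0")
  structure(list(window_size = window_size,
                 node_offset = as.integer(node_offset),
                 prefilter_kernel = prefilter_kernel,
                 search_radius = as.integer(search_radius),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "dvct_config")
}

check_config <- function(cfg) {
  if (!inherits(cfg, "dvct_config")) {
    stopf("cfg must come from correlation_config()")
  }
  cfg
}

#' 3D median prefilter
#'
#' Per-voxel median over a `kernel^3` cube with edge-replicated borders,
#' applied to both volumes before correlation to suppress reconstruction
#' noise. `kernel = 1` is the identity.
#'
#' @param v a [volume()].
#' @param kernel odd cube edge in voxels.
#' @return the filtered [volume()].
#' @export
prefilter <- function(v, kernel = 13) {
  check_volume(v)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L != 1L) stopf("kernel must be odd and >= 1")
  if (kernel == 1L) return(v)
  volume(cpp_median_filter3(v$data, kernel), voxel_size = v$voxel_size,
         origin = v$origin)
}

node_to0 <- function(node) {
  node <- as.numeric(node)
  if (length(node) != 3L) stopf("node must be (z, y, x)")
  node - 1
}

#' Integer-voxel displacement search
#'
#' Zero-mean normalized cross-correlation between the reference window
#' centered at `node` and candidate windows in the deformed volume,
#' maximized by steepest-gradient hill climbing over the 26-neighborhood of
#' integer displacements starting at `init`, bounded per axis by
#' `cfg$search_radius`. `exhaustive = TRUE` scans the whole search cube
#' instead (slow; the deterministic fallback).
#'
#' @param ref,def [volume()]s (already prefiltered).
#' @param node 1-based voxel coordinates `(z, y, x)` of the window center.
#' @param cfg a [correlation_config()].
#' @param init integer displacement starting point.
#' @param exhaustive scan the full search cube instead of hill climbing.
#' @return list with integer `disp` `(z, y, x)` and its `ncc`.
#' @export
integer_search <- function(ref, def, node, cfg = correlation_config(),
                           init = c(0, 0, 0), exhaustive = FALSE) {
  check_volume(ref)
  check_volume(def)
  check_config(cfg)
  res <- cpp_integer_search(ref$data, def$data, node_to0(node),
                            cfg$window_size, cfg$search_radius,
                            as.integer(round(init)), exhaustive)
  list(disp = as.numeric(res$disp), ncc = res$ncc)
}

#' Sub-voxel displacement refinement (3D Lucas-Kanade)
#'
#' Gauss-Newton minimization of the sum of squared intensity differences
#' between the window pair under a 12-parameter local affine warp
#' `d -> node + d + u + A d` (trilinear intensity interpolation with its
#' exact analytic gradient, plus a backtracking line search). The fit is
#' run in the inverse-compositional direction - the pristine reference
#' volume is warped onto the deformed-state window and the fitted map is
#' inverted - which cancels the resampling bias a forward fit suffers when
#' the deformed volume is itself an interpolated image. Iterates until the
#' update norm falls below `cfg$tolerance` or `cfg$max_iterations` is hit;
#' a hit cap or singular normal matrix yields status `"unconverged"` (data,
#' not an error).
#'
#' @param ref,def [volume()]s (already prefiltered).
#' @param node 1-based window center `(z, y, x)`.
#' @param init initial displacement, normally from [integer_search()].
#' @param cfg a [correlation_config()].
#' @return list with sub-voxel `u`, local affine deviation matrix `A` (the
#'   local deformation gradient is `I + A`), `status`, `iterations`, `ncc`.
#' @export
subvoxel_refine <- function(ref, def, node, init = c(0, 0, 0),
                            cfg = correlation_config()) {
  check_volume(ref)
  check_volume(def)
  check_config(cfg)
  res <- cpp_lk_refine(ref$data, def$data, node_to0(node), cfg$window_size,
                       as.numeric(init), cfg$tolerance, cfg$max_iterations)
  list(u = as.numeric(res$u), A = res$A,
       status = if (res$converged) "converged" else "unconverged",
       iterations = res$iterations, ncc = res$ncc)
}

#' Construct a displacement field
#'
#' Nodes live on a rectangular lattice (`grid_index` gives each node's
#' lattice coordinates; planar fields have a constant third coordinate).
#'
#' @param nodes `n x 3` reference-state voxel coordinates (1-based).
#' @param u `n x 3` displacements, voxels.
#' @param ncc correlation coefficient per node.
#' @param status character per node: `"converged"`, `"unconverged"` or
#'   `"filtered-replaced"`.
#' @param grid_index `n x 3` integer lattice coordinates.
#' @return a `dvct_field` data.frame.
#' @export
displacement_field <- function(nodes, u, ncc, status, grid_index) {
  n <- nrow(nodes)
  if (nrow(u) != n || length(ncc) != n || length(status) != n ||
      nrow(grid_index) != n) {
    stopf("field components must have one entry per node")
  }
  conv <- status == "converged"
  if (any(abs(ncc[conv]) > 1 + 1e-12, na.rm = TRUE)) {
    stopf("|ncc| must be <= 1 for converged nodes")
  }
  if (any(!is.finite(u[status != "unconverged", ]))) {
    stopf("u must be finite for non-unconverged nodes")
  }
  structure(data.frame(gi = grid_index[, 1], gj = grid_index[, 2],
                       gk = grid_index[, 3], z = nodes[, 1], y = nodes[, 2],
                       x = nodes[, 3], uz = u[, 1], uy = u[, 2],
                       ux = u[, 3], ncc = ncc, status = status,
                       stringsAsFactors = FALSE),
            class = c("dvct_field", "data.frame"))
}

#' Correlate a plane slab between two volumes
#'
#' Nodes are placed on the medial plane of a slab (normal along `axis`, the
#' paper-default thickness is 100 voxels) with spacing `cfg$node_offset`,
#' and each node is processed by the two-step correlation. Nodes whose
#' window or search range would leave the volume are never instantiated;
#' zero-variance windows come back `"unconverged"`.
#'
#' @param ref,def [volume()]s of identical shape.
#' @param axis slab normal: `"z"`, `"y"` or `"x"` (or 1..3).
#' @param index 1-based position of the medial plane along `axis`.
#' @param slab_thickness slab extent along `axis`, voxels.
#' @param cfg a [correlation_config()].
#' @param apply_prefilter median-prefilter both volumes first (set `FALSE`
#'   when passing already-filtered volumes).
#' @return a [displacement_field()].
#' @export
correlate_plane <- function(ref, def, axis = "x", index,
                            slab_thickness = 100,
                            cfg = correlation_config(),
                            apply_prefilter = TRUE) {
  check_volume(ref)
  check_volume(def)
  check_config(cfg)
  if (!identical(dim(ref$data), dim(def$data))) {
    stopf("ref and def must have identical shapes")
  }
  ax <- if (is.character(axis)) match(axis, c("z", "y", "x")) else
    as.integer(axis)
  if (is.na(ax) || ax < 1L || ax > 3L) stopf("axis must be z, y or x")
  d <- dim(ref$data)
  half_slab <- (slab_thickness - 1) / 2
  if (index - floor(half_slab) < 1 || index + ceiling(half_slab) > d[ax]) {
    stopf("slab [%s +- %g] leaves the volume along axis %d", index,
          half_slab, ax)
  }
  if (apply_prefilter) {
    ref <- prefilter(ref, cfg$prefilter_kernel)
    def <- prefilter(def, cfg$prefilter_kernel)
  }
  margin <- cfg$window_size %/% 2L + cfg$search_radius + 1L
  inplane <- setdiff(1:3, ax)
  grids <- lapply(inplane, function(a) {
    if (d[a] < 2L * margin + 1L) integer(0) else
      seq.int(margin + 1L, d[a] - margin, by = cfg$node_offset)
  })
  if (any(vapply(grids, length, integer(1L)) == 0L)) {
    stopf("volume too small for window %d with search radius %d",
          cfg$window_size, cfg$search_radius)
  }
  gi <- rep(seq_along(grids[[1]]), times = length(grids[[2]]))
  gj <- rep(seq_along(grids[[2]]), each = length(grids[[1]]))
  nodes <- matrix(index, length(gi), 3)
  nodes[, inplane[1]] <- grids[[1]][gi]
  nodes[, inplane[2]] <- grids[[2]][gj]
  res <- cpp_track_nodes(ref$data, def$data, nodes - 1L,
                         matrix(0, nrow(nodes), 3), cfg$window_size,
                         cfg$search_radius, cfg$tolerance,
                         cfg$max_iterations)
  status <- ifelse(res$converged, "converged", "unconverged")
  displacement_field(nodes, res$u, res$ncc, status,
                     cbind(gi, gj, 1L))
}

field_neighbor_index <- function(f, radius) {
  # list of neighbor row indices per node (Chebyshev distance <= radius on
  # the lattice, excluding self)
  key <- paste(f$gi, f$gj, f$gk)
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in seq_len(nrow(f))) assign(key[r], r, envir = lookup)
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius,
                      dk = -radius:radius)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  lapply(seq_len(nrow(f)), function(r) {
    ks <- paste(f$gi[r] + offs$di, f$gj[r] + offs$dj, f$gk[r] + offs$dk)
    hits <- vapply(ks, function(k) {
      if (exists(k, envir = lookup, inherits = FALSE)) {
        get(k, envir = lookup)
      } else {
        NA_integer_
      }
    }, integer(1L), USE.NAMES = FALSE)
    hits[!is.na(hits)]
  })
}

#' Two-step displacement-field filtering
#'
#' Step 1 replaces unconverged nodes by the component-wise median of their
#' converged lattice neighbors; step 2 replaces nodes whose displacement
#' deviates from the local median by more than `outlier_k` times the local
#' median absolute deviation (plus a small absolute floor guarding against
#' near-zero MAD in smooth fields). Replaced nodes are flagged
#' `"filtered-replaced"`.
#'
#' @param f a [displacement_field()].
#' @param neighborhood lattice radius of the neighbor set.
#' @param outlier_k MAD multiplier of the outlier rule.
#' @param mad_floor absolute deviation floor, voxels.
#' @return the filtered [displacement_field()].
#' @export
filter_field <- function(f, neighborhood = 1, outlier_k = 3,
                         mad_floor = 0.05) {
  if (!inherits(f, "dvct_field")) stopf("f must be a displacement field")
  if (nrow(f) == 0L) stopf("field is empty")
  if (all(f$status == "unconverged")) stopf("all nodes unconverged")
  nb <- field_neighbor_index(f, neighborhood)
  ucols <- c("uz", "uy", "ux")
  # step 1: invalid (unconverged) values
  for (r in which(f$status == "unconverged")) {
    good <- nb[[r]][f$status[nb[[r]]] == "converged"]
    if (length(good) == 0L) next
    for (cc in ucols) f[[cc]][r] <- median(f[[cc]][good])
    f$status[r] <- "filtered-replaced"
  }
  # step 2: non-physical values (component-wise median/MAD outlier rule)
  u0 <- as.matrix(f[, ucols])
  replace_r <- logical(nrow(f))
  med_r <- matrix(0, nrow(f), 3)
  for (r in seq_len(nrow(f))) {
    if (f$status[r] == "unconverged") next
    good <- nb[[r]][f$status[nb[[r]]] != "unconverged"]
    if (length(good) < 3L) next
    for (a in 1:3) {
      med <- median(u0[good, a])
      madv <- mad(u0[good, a])
      med_r[r, a] <- med
      if (abs(u0[r, a] - med) > outlier_k * madv + mad_floor) {
        replace_r[r] <- TRUE
      }
    }
  }
  for (r in which(replace_r)) {
    f$uz[r] <- med_r[r, 1]
    f$uy[r] <- med_r[r, 2]
    f$ux[r] <- med_r[r, 3]
    f$status[r] <- "filtered-replaced"
  }
  f
}

#' Mean-bias error
#'
#' `MBE = mean(P - O)` between expected values `P` (the prescribed
#' displacements) and observed values `O` (the DVC result).
#'
#' @param p,o equal-length numeric vectors, length >= 1.
#' @return the mean bias.
#' @export
mbe <- function(p, o) {
  if (length(p) != length(o)) stopf("P and O must have equal lengths")
  if (length(p) == 0L) stopf("empty input")
  mean(p - o)
}

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((P - O)^2))`; always at least `|MBE|`.
#'
#' @inheritParams mbe
#' @return the RMS error.
#' @export
rmse <- function(p, o) {
  if (length(p) != length(o)) stopf("P and O must have equal lengths")
  if (length(p) == 0L) stopf("empty input")
  sqrt(mean((p - o)^2))
}

#' Window-size calibration by virtual rigid-body motion
#'
#' The virtual experiment: the volume is numerically shifted in-plane in
#' `n_steps` rigid steps of `step_shift` voxels (default 4 voxels in each of
#' the two in-plane axes, five steps, i.e. a total motion of 20 + 20 voxels
#' whose ideal magnitude is `sqrt(800) = 28.2842` px) and all non-void nodes
#' of a region are tracked through every step for each candidate window
#' size. Per window the table reports the unconverged node count, the mean
#' final in-plane displacement magnitude (`mean_uYZ`), the standard
#' deviation of the deviation from the ideal magnitude across all steps
#' (`sigma_YZ`), and MBE/RMSE at the final step.
#'
#' The volume is median-prefiltered once and the shifted copies are derived
#' from the filtered data (integer shifting commutes with the median
#' filter away from borders).
#'
#' @param v a [volume()] or `dvct_phantom`.
#' @param window_sizes even window edges to sweep.
#' @param n_steps number of virtual load steps.
#' @param step_shift per-step shift `(z, y, x)` in voxels (two in-plane
#'   components nonzero).
#' @param region optional list with integer vectors `z`, `y`, `x` of node
#'   coordinates (a box); default a centered `40 x 40 x 1` block in the
#'   plane of motion.
#' @param cfg base [correlation_config()] (its `window_size` is overridden
#'   by the sweep).
#' @param void_threshold intensity below which a node is treated as void and
#'   skipped; default the phantom's level midpoint or an Otsu threshold.
#' @return a `dvct_calibration` data.frame with columns `window_size`,
#'   `elapsed_s`, `unconverged`, `mean_uYZ`, `sigma_YZ`, `mbe`, `rmse`.
#' @export
calibrate_window <- function(v, window_sizes = seq(6, 20, by = 2),
                             n_steps = 5, step_shift = c(4, 4, 0),
                             region = NULL, cfg = correlation_config(),
                             void_threshold = NULL) {
  if (inherits(v, "dvct_phantom")) {
    if (is.null(void_threshold)) {
      void_threshold <- (v$spec$void_level + v$spec$tissue_level) / 2
    }
    v <- v$volume
  }
  check_volume(v)
  check_config(cfg)
  step_shift <- as.numeric(step_shift)
  if (length(step_shift) != 3L || !(sum(step_shift != 0) %in% c(0L, 2L))) {
    stopf("step_shift must move exactly two (in-plane) axes, or none")
  }
  if (any(step_shift != round(step_shift))) {
    stopf("step_shift must be integer voxels (numerical rigid-body motion)")
  }
  if (is.null(void_threshold)) void_threshold <- otsu_threshold(v$data)
  d <- dim(v$data)
  inplane <- if (all(step_shift == 0)) 1:2 else which(step_shift != 0)
  if (is.null(region)) {
    region <- list()
    for (a in 1:3) {
      region[[c("z", "y", "x")[a]]] <- if (a %in% inplane) {
        seq.int(floor(d[a] / 2) - 19L, floor(d[a] / 2) + 20L)
      } else {
        floor(d[a] / 2)
      }
    }
  }
  nodes <- as.matrix(expand.grid(z = region$z, y = region$y, x = region$x))
  keep <- v$data[nodes] > void_threshold
  nodes <- nodes[keep, , drop = FALSE]
  if (nrow(nodes) == 0L) stopf("no non-void nodes in the region")
  vf <- prefilter(v, cfg$prefilter_kernel)
  total <- n_steps * step_shift
  maxw <- max(window_sizes)
  for (a in 1:3) {
    lo <- min(nodes[, a]) - maxw / 2 - cfg$search_radius
    hi <- max(nodes[, a]) + maxw / 2 + cfg$search_radius + abs(total[a])
    if (lo < 1 || hi > d[a]) {
      stopf("cumulative motion pushes the tracked region out of bounds on axis %d",
            a)
    }
  }
  # deformed states: exact integer shifts of the filtered volume
  defs <- lapply(seq_len(n_steps), function(s) {
    sh <- s * step_shift
    tr <- affine_transform(diag(3), sh)
    apply_deformation(vf, tr, fill = min(vf$data))
  })
  ideal_step <- vapply(seq_len(n_steps), function(s) {
    sqrt(sum((s * step_shift[inplane])^2))
  }, numeric(1L))
  rows <- lapply(window_sizes, function(w) {
    t0 <- proc.time()[["elapsed"]]
    wcfg <- cfg
    wcfg$window_size <- as.integer(w)
    uprev <- matrix(0, nrow(nodes), 3)
    bad <- logical(nrow(nodes))
    dev_all <- numeric(0)
    ufin <- NULL
    for (s in seq_len(n_steps)) {
      res <- cpp_track_nodes(vf$data, defs[[s]]$data, nodes - 1L, uprev,
                             wcfg$window_size, wcfg$search_radius,
                             wcfg$tolerance, wcfg$max_iterations)
      bad <- bad | !res$converged | apply(!is.finite(res$u), 1, any)
      u <- res$u
      u[bad, ] <- NA_real_
      umag <- sqrt(u[, inplane[1]]^2 + u[, inplane[2]]^2)
      dev_all <- c(dev_all, (umag - ideal_step[s])[!bad])
      # seed the next step from this one; diverged nodes restart at the
      # prescribed position so later steps stay within search range
      uprev <- u
      if (any(bad)) {
        uprev[bad, ] <- matrix(s * step_shift, sum(bad), 3, byrow = TRUE)
      }
      ufin <- umag
    }
    ok <- !bad
    p <- rep(ideal_step[n_steps], sum(ok))
    data.frame(window_size = w, elapsed_s = proc.time()[["elapsed"]] - t0,
               unconverged = sum(bad), mean_uYZ = mean(ufin[ok]),
               sigma_YZ = if (length(dev_all) > 1L) sd(dev_all) else 0,
               mbe = mbe(p, ufin[ok]), rmse = rmse(p, ufin[ok]))
  })
  structure(do.call(rbind, rows), class = c("dvct_calibration",
                                            "data.frame"))
}
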