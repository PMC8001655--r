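# Local least-squares alignment of the loaded volume to the reference and
# differential-tomography blending Vb = Vr + m * Vl. Alignment uses a small
# cube of DVC support points near (but standing off from) a crack tip, a
# weighted least-squares transformation fit, and trilinear resampling.

#' Construct an affine transform
#'
#' Maps 0-based voxel coordinates `x` (z, y, x order) to `linear %*% x +
#' translation`. `kind = "rigid"` additionally requires an orthonormal
#' linear part with determinant +1.
#'
#' @param linear 3x3 matrix, invertible.
#' @param translation 3-vector, voxels.
#' @param kind `"rigid"` or `"general"`.
#' @return a `dvct_affine`.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0),
                             kind = c("general", "rigid")) {
  kind <- match.arg(kind)
  linear <- unname(as.matrix(linear))
  translation <- unname(as.numeric(translation))
  if (!identical(dim(linear), c(3L, 3L)) || length(translation) != 3L) {
    stopf("linear must be 3x3 and translation length 3")
  }
  if (!all(is.finite(linear)) || !all(is.finite(translation))) {
    stopf("transform must be finite")
  }
  if (abs(det(linear)) < 1e-12) stopf("linear part is not invertible")
  if (kind == "rigid") {
    if (max(abs(crossprod(linear) - diag(3))) > 1e-6 ||
        abs(det(linear) - 1) > 1e-6) {
      stopf("rigid transform requires an orthonormal linear part with det +1")
    }
  }
  structure(list(linear = linear, translation = translation, kind = kind),
            class = "dvct_affine")
}

#' @export
print.dvct_affine <- function(x, ...) {
  cat(sprintf("dvct_affine (%s):\n", x$kind))
  m <- cbind(x$linear, x$translation)
  dimnames(m) <- list(c("z", "y", "x"), c("z", "y", "x", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Pick DVC support points near a crack tip
#'
#' Returns a 5 x 5 x 5 cube of 125 node coordinates centered at the crack
#' tip offset along `direction` by `standoff` voxels: close enough to the
#' crack tip for a local alignment, far enough that the void does not enter
#' the correlation windows. Supplying `void_mask` makes any grid point
#' inside the void an error.
#'
#' @param v a [volume()].
#' @param crack_tip 1-based voxel coordinates `(z, y, x)` of the crack tip.
#' @param standoff offset distance from the tip, voxels.
#' @param direction outward in-plane unit direction away from the crack
#'   (normalized internally).
#' @param spacing grid spacing, voxels.
#' @param void_mask optional logical array of void voxels.
#' @return `125 x 3` integer matrix of node coordinates.
#' @export
pick_support_points <- function(v, crack_tip, standoff,
                                direction = c(0, 1, 0), spacing = 2,
                                void_mask = NULL) {
  check_volume(v)
  direction <- as.numeric(direction)
  if (sum(direction^2) == 0) stopf("direction must be nonzero")
  direction <- direction / sqrt(sum(direction^2))
  base <- as.numeric(crack_tip) + standoff * direction
  offs <- as.matrix(expand.grid(z = -2:2, y = -2:2, x = -2:2)) * spacing
  pts <- round(sweep(offs, 2, base, `+`))
  d <- dim(v$data)
  if (any(pts < 1) || any(sweep(pts, 2, d, `>`))) {
    stopf("support grid leaves the volume; increase margins or reduce standoff")
  }
  if (!is.null(void_mask) && any(void_mask[pts])) {
    stopf("support grid intersects the void; increase standoff")
  }
  storage.mode(pts) <- "integer"
  dimnames(pts) <- list(NULL, c("z", "y", "x"))
  pts
}

#' Fit a transformation to point correspondences
#'
#' Weighted least-squares minimizer of `sum w_i ||T(ref_i) - def_i||^2`:
#' `kind = "general"` solves a weighted linear least-squares problem for a
#' full affine; `kind = "rigid"` solves a weighted orthogonal Procrustes
#' problem (Kabsch, determinant-corrected).
#'
#' @param ref_points,def_points `n x 3` coordinate matrices.
#' @param weights optional nonnegative weights (e.g. NCC values).
#' @param kind `"general"` (>= 4 non-coplanar pairs) or `"rigid"` (>= 3
#'   non-collinear pairs).
#' @return an [affine_transform()].
#' @export
fit_transform <- function(ref_points, def_points, weights = NULL,
                          kind = c("general", "rigid")) {
  kind <- match.arg(kind)
  r <- as.matrix(ref_points)
  q <- as.matrix(def_points)
  if (!identical(dim(r), dim(q)) || ncol(r) != 3L) {
    stopf("point sets must be matching n x 3 matrices")
  }
  n <- nrow(r)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    stopf("weights must be nonnegative, one per point")
  }
  if (sum(weights > 0) < ifelse(kind == "general", 4L, 3L)) {
    stopf("insufficient points for a %s fit", kind)
  }
  wbar <- weights / sum(weights)
  rc <- colSums(r * wbar)
  qc <- colSums(q * wbar)
  rr <- sweep(r, 2, rc)
  qq <- sweep(q, 2, qc)
  sv <- svd(crossprod(rr * weights, rr))
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  if (kind == "general") {
    if (rank < 3L) stopf("degenerate geometry: points are coplanar")
    lin <- t(solve(crossprod(rr * weights, rr), crossprod(rr * weights, qq)))
    trans <- qc - as.numeric(lin %*% rc)
    return(affine_transform(lin, trans, "general"))
  }
  if (rank < 2L) stopf("degenerate geometry: points are collinear")
  h <- crossprod(rr * weights, qq)  # sum w (r - rbar)(q - qbar)^T
  sv <- svd(h)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  lin <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  trans <- qc - as.numeric(lin %*% rc)
  affine_transform(lin, trans, "rigid")
}

#' Resample a volume under a transform
#'
#' Output voxel `x` takes the intensity of `v` at `t(x)` by trilinear
#' interpolation; coordinates mapping outside the domain get `fill` (air
#' level). With `t` fitted from reference -> loaded correspondences this
#' aligns the loaded volume onto the reference grid.
#'
#' @param v a [volume()].
#' @param t an [affine_transform()].
#' @param fill out-of-domain intensity; default `min(v$data)`.
#' @return the resampled [volume()].
#' @export
resample_volume <- function(v, t, fill = NULL) {
  check_volume(v)
  if (!inherits(t, "dvct_affine")) stopf("t must be an affine_transform")
  if (is.null(fill)) fill <- min(v$data)
  volume(cpp_resample_affine(v$data, t$linear, t$translation, fill),
         voxel_size = v$voxel_size, origin = v$origin)
}

#' Blend reference and loaded volumes (differential tomography)
#'
#' `Vb = Vr + m * Vl`, voxelwise in floating point with no clipping. In the
#' blended volume, voids present in both states stay dark while
#' newly-formed cracks (void in the loaded state only) drop far below the
#' tissue level, making them visible at high contrast.
#'
#' @param vr reference-state [volume()].
#' @param vl loaded-state [volume()], same shape and voxel size.
#' @param m integer multiplier (the optimum found by contrast inspection is
#'   20).
#' @return the blended [volume()].
#' @export
blend <- function(vr, vl, m = 20) {
  check_volume(vr)
  check_volume(vl)
  if (!identical(dim(vr$data), dim(vl$data))) {
    stopf("volumes must have identical shapes")
  }
  if (!isTRUE(all.equal(vr$voxel_size, vl$voxel_size))) {
    stopf("volumes must have identical voxel sizes")
  }
  if (m != round(m)) stopf("m must be an integer")
  volume(vr$data + m * vl$data, voxel_size = vr$voxel_size,
         origin = vr$origin)
}

#' Select the blending multiplier by contrast
#'
#' For every `m` in `m_range` the blended volume's contrast-to-noise ratio
#' between the sampled tissue and void populations is computed,
#' `CNR(m) = |mean_tissue - mean_void| / pooled SD`, and the arg-max `m` is
#' returned together with the full curve. This is the computable version of
#' the iterative visual contrast inspection used to pick `m`.
#'
#' @param vr,vl reference and loaded [volume()]s.
#' @param void_mask,tissue_mask disjoint non-empty logical arrays sampling
#'   the two populations.
#' @param m_range candidate integer multipliers (paper interval 2..50).
#' @return list with `m` (smallest arg-max) and `curve` (data.frame `m`,
#'   `cnr`).
#' @export
select_multiplier <- function(vr, vl, void_mask, tissue_mask,
                              m_range = 2:50) {
  check_volume(vr)
  check_volume(vl)
  if (!any(void_mask) || !any(tissue_mask)) stopf("masks must be non-empty")
  if (any(void_mask & tissue_mask)) stopf("masks must be disjoint")
  cnr <- vapply(m_range, function(m) {
    vb <- vr$data + m * vl$data
    tv <- vb[tissue_mask]
    vv <- vb[void_mask]
    num <- abs(mean(tv) - mean(vv))
    n1 <- length(tv)
    n2 <- length(vv)
    pooled <- sqrt(((n1 - 1) * var_or0(tv) + (n2 - 1) * var_or0(vv)) /
                     max(n1 + n2 - 2, 1))
    if (pooled == 0) {
      if (num == 0) 0 else Inf
    } else {
      num / pooled
    }
  }, numeric(1L))
  list(m = m_range[which.max(cnr)], curve = data.frame(m = m_range,
                                                       cnr = cnr))
}

var_or0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)

#' Local crack-tip registration of loaded to reference volume
#'
#' The end-to-end local alignment: DVC-track the 125 support points from
#' [pick_support_points()] between the reference and loaded volumes, keep
#' points with sufficiently high correlation coefficient, and fit a
#' transformation by weighted least squares.
#'
#' @param ref,def reference and loaded [volume()]s.
#' @param crack_tip,standoff,direction,void_mask see
#'   [pick_support_points()].
#' @param kind `"general"` or `"rigid"`.
#' @param cfg a [correlation_config()].
#' @param min_ncc correlation-coefficient threshold for a point to enter
#'   the fit.
#' @param apply_prefilter median-prefilter both volumes first.
#' @return list with `transform` (an [affine_transform()]), `points`
#'   (support coordinates), `u` (their displacements) and `ncc`.
#' @export
register_local <- function(ref, def, crack_tip, standoff,
                           direction = c(0, 1, 0), void_mask = NULL,
                           kind = c("general", "rigid"),
                           cfg = correlation_config(), min_ncc = 0.9,
                           apply_prefilter = TRUE) {
  kind <- match.arg(kind)
  check_volume(ref)
  check_volume(def)
  check_config(cfg)
  pts <- pick_support_points(ref, crack_tip, standoff, direction,
                             void_mask = void_mask)
  if (apply_prefilter) {
    ref <- prefilter(ref, cfg$prefilter_kernel)
    def <- prefilter(def, cfg$prefilter_kernel)
  }
  res <- cpp_track_nodes(ref$data, def$data, pts - 1L,
                         matrix(0, nrow(pts), 3), cfg$window_size,
                         cfg$search_radius, cfg$tolerance,
                         cfg$max_iterations)
  good <- res$converged & is.finite(res$ncc) & res$ncc >= min_ncc
  if (sum(good) < 4L) {
    stopf("only %d support points exceed NCC %.2f; cannot fit", sum(good),
          min_ncc)
  }
  tr <- fit_transform(pts[good, , drop = FALSE],
                      pts[good, , drop = FALSE] +
                        res$u[good, , drop = FALSE],
                      weights = res$ncc[good], kind = kind)
  list(transform = tr, points = pts, u = res$u, ncc = res$ncc)
}
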