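# Crack metrology: line intensity profiles, FWHM width of a crack dip,
# void segmentation with surface exclusion, and mask-based width/length
# measurement (distance transform / geodesic diameter).

#' Extract a line intensity profile
#'
#' Samples intensities at uniform steps along the segment `p0 -> p1`
#' (physical micrometre coordinates) by trilinear interpolation in a volume
#' or bilinear interpolation in a 2D slice.
#'
#' @param v a [volume()], or a numeric matrix (2D slice).
#' @param p0,p1 segment endpoints in micrometres (`(z, y, x)` for volumes,
#'   `(row, col)` for matrices, relative to the volume origin).
#' @param step sampling step in micrometres; default half the smallest
#'   voxel/pixel edge.
#' @param pixel_size pixel size for matrix input, micrometres.
#' @return a `dvct_profile`: `positions` (distance from `p0`, um),
#'   `intensities`, `step`.
#' @export
extract_profile <- function(v, p0, p1, step = NULL, pixel_size = 1) {
  two_d <- is.matrix(v)
  if (two_d) {
    vs <- as.numeric(rep(pixel_size, length.out = 2L))
    org <- c(0, 0)
    nd <- 2L
  } else {
    check_volume(v)
    vs <- v$voxel_size
    org <- v$origin
    nd <- 3L
  }
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  if (length(p0) != nd || length(p1) != nd) {
    stopf("endpoints must have %d coordinates", nd)
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (is.null(step)) step <- min(vs) / 2
  if (len == 0 || step <= 0) stopf("degenerate segment or step")
  tpar <- seq(0, len, by = step)
  pts <- outer(tpar / len, p1 - p0) + matrix(p0, length(tpar), nd,
                                             byrow = TRUE)
  # to continuous 0-based voxel coordinates
  idx <- sweep(sweep(pts, 2, org), 2, vs, `/`)
  vals <- if (two_d) cpp_sample_line2d(v, idx) else
    cpp_sample_line(v$data, idx)
  if (anyNA(vals)) stopf("segment exits the volume domain")
  if (length(vals) < 5L) stopf("profile needs at least 5 samples")
  structure(list(positions = tpar, intensities = as.numeric(vals),
                 step = step),
            class = "dvct_profile")
}

#' Full width at half maximum of a profile feature
#'
#' The baseline is the median of the outer 20% of samples (10% each end),
#' the extremum is the profile minimum (`feature = "dip"`, a crack) or
#' maximum (`"peak"`), the half level is their mean, and the two crossings
#' are located by linear interpolation between bracketing samples. Invariant
#' to affine intensity rescaling and to profile reversal.
#'
#' @param p a `dvct_profile`, or a list with `positions` and `intensities`.
#' @param feature `"dip"` or `"peak"`. Crack features in plain CT slices are
#'   dips; blended volumes can invert contrast, hence the explicit flag.
#' @return list with `width` (um), `left`, `right` crossing positions,
#'   `baseline`, `half_level` and `extremum_position`.
#' @export
fwhm <- function(p, feature = c("dip", "peak")) {
  feature <- match.arg(feature)
  pos <- p$positions
  ints <- p$intensities
  n <- length(ints)
  if (n < 5L) stopf("profile needs at least 5 samples")
  if (any(diff(pos) <= 0)) stopf("positions must be strictly increasing")
  k <- max(1L, floor(0.1 * n))
  baseline <- median(c(ints[seq_len(k)], ints[n - seq_len(k) + 1L]))
  sgn <- if (feature == "dip") -1 else 1
  w <- sgn * ints
  ext <- which(w == max(w))
  if (length(ext) > 1L && any(diff(ext) > 1L)) {
    stopf("multiple equal extrema; profile is not a single %s", feature)
  }
  ext <- ext[ceiling(length(ext) / 2)]
  half <- (baseline + ints[ext]) / 2
  cross <- function(side) {
    idx <- if (side == "left") seq(ext, 1L) else seq(ext, n)
    above <- which(sgn * ints[idx] <= sgn * half)
    if (length(above) == 0L || above[1L] == 1L) {
      stopf("no half-maximum crossing on the %s side", side)
    }
    i2 <- idx[above[1L]]                 # first sample at/beyond half level
    i1 <- idx[above[1L] - 1L]            # last sample inside the feature
    if (ints[i2] == ints[i1]) return(pos[i2])
    pos[i1] + (half - ints[i1]) / (ints[i2] - ints[i1]) * (pos[i2] -
                                                             pos[i1])
  }
  left <- cross("left")
  right <- cross("right")
  list(width = right - left, left = left, right = right,
       baseline = baseline, half_level = half,
       extremum_position = pos[ext])
}

#' Otsu intensity threshold
#'
#' Maximizes the between-class variance over a 256-bin histogram.
#'
#' @param x numeric values (non-constant).
#' @param nbins histogram bin count.
#' @return the threshold intensity.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stopf("cannot threshold a constant volume")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  centers[which.max(sigma_b)]
}

#' Segment void space with surface exclusion
#'
#' Thresholds the volume, labels connected components of the sub-threshold
#' voxels, and removes every component touching the outer surface shell
#' (within `exclusion_margin` of the volume border) - this drops the
#' surrounding air, through-going canals and preparation-induced surface
#' cracks, leaving the internal microcracks.
#'
#' @param vb a [volume()] (plain or blended).
#' @param threshold intensity threshold or `"otsu"`.
#' @param exclusion_margin shell thickness in micrometres.
#' @param connectivity 6 or 26.
#' @return logical array of retained void voxels, with the component
#'   labelling in attribute `labels`.
#' @export
segment_voids <- function(vb, threshold = "otsu", exclusion_margin = 50,
                          connectivity = 26L) {
  check_volume(vb)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vb$data) else
    as.numeric(threshold)
  mask <- vb$data < thr
  d <- dim(vb$data)
  lab <- cpp_label_components(mask, d, as.integer(connectivity))
  if (max(lab) == 0L) {
    out <- array(FALSE, d)
    attr(out, "labels") <- lab
    attr(out, "threshold") <- thr
    return(out)
  }
  mv <- pmax(1L, as.integer(ceiling(exclusion_margin / vb$voxel_size)))
  shell <- array(FALSE, d)
  shell[c(seq_len(min(mv[1], d[1])),
          seq.int(max(1L, d[1] - mv[1] + 1L), d[1])), , ] <- TRUE
  shell[, c(seq_len(min(mv[2], d[2])),
            seq.int(max(1L, d[2] - mv[2] + 1L), d[2])), ] <- TRUE
  shell[, , c(seq_len(min(mv[3], d[3])),
              seq.int(max(1L, d[3] - mv[3] + 1L), d[3]))] <- TRUE
  drop_labels <- unique(lab[shell & mask])
  out <- mask & !(array(lab %in% drop_labels, d))
  attr(out, "labels") <- lab
  attr(out, "threshold") <- thr
  out
}

#' Largest connected component of a voxel mask
#'
#' Convenience selector for feeding a single crack from [segment_voids()]
#' into [measure_crack()].
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return logical array keeping only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), d, as.integer(connectivity))
  if (max(lab) == 0L) return(array(FALSE, d))
  counts <- tabulate(lab[lab > 0L])
  array(lab == which.max(counts), d)
}

#' Measure a segmented microcrack
#'
#' Width is derived from the Euclidean distance transform inside the mask
#' (`2 * max(EDT) - voxel_size`, which is exact for axis-aligned slabs of
#' whole-voxel thickness); length is the geodesic diameter of the thin mask
#' (double-sweep Dijkstra with a 5x5x5 neighborhood, approximating the
#' longest path along the medial curve).
#'
#' @param mask connected, non-empty logical array of crack voxels.
#' @param voxel_size voxel edge, micrometres (scalar or length 3).
#' @return a `dvct_crack_measurement`: `width` and `length` in um,
#'   `n_voxels`, `method = "mask-based"`.
#' @export
measure_crack <- function(mask, voxel_size) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stopf("mask must be a 3D logical array")
  }
  voxel_size <- as_len3(voxel_size, "voxel_size")
  d <- dim(mask)
  if (!any(mask)) stopf("empty mask")
  lab <- cpp_label_components(as.logical(mask), d, 26L)
  if (max(lab) > 1L) stopf("mask must be a single connected component")
  edt <- cpp_edt(as.logical(mask), d, voxel_size)
  mx <- max(edt[mask])
  width <- if (is.finite(mx)) 2 * mx - min(voxel_size) else NA_real_
  coords <- which(array(mask, d), arr.ind = TRUE) - 1L
  geo <- cpp_geodesic_diameter(coords, voxel_size)
  structure(list(width = width, length = geo$length,
                 n_voxels = sum(mask), method = "mask-based"),
            class = "dvct_crack_measurement")
}

#' @export
print.dvct_crack_measurement <- function(x, ...) {
  cat(sprintf("crack: width %.3g um, length %.4g um (%d voxels, %s)\n",
              x$width, x$length, x$n_voxels, x$method))
  invisible(x)
}
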