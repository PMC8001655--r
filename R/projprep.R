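# Projection-level corrections: scan-plan construction, flat-field
# normalization, and focal-spot drift estimation/compensation from the
# repeated fixed-angle reference exposures interleaved between sub-scans.

#' Build a sub-scan acquisition plan
#'
#' The full rotation is covered by `n_subscans` interleaved sub-scans of
#' `n_per_subscan` projections each; sub-scan `k` (1-based) covers angles
#' `subscan_shift_deg * (k - 1) + 360 * j / n_per_subscan`. Each sub-scan
#' additionally opens with one reference exposure at a fixed angle, used for
#' drift estimation. The plan reports whether the merged angle set is
#' uniformly spaced (which requires `subscan_shift_deg = 360 /
#' (n_per_subscan * n_subscans)`).
#'
#' @param n_subscans,n_per_subscan positive counts.
#' @param subscan_shift_deg angular shift between consecutive sub-scans;
#'   `NULL` picks the value that makes the merged set equiangular.
#' @param reference_angle_deg fixed angle of the repeated reference exposure.
#' @return a `dvct_scan_plan` with the full `angles` list (per sub-scan), an
#'   `equiangular` flag and the merged angular `spacing_deg` when uniform.
#' @examples
#' plan <- build_scan_plan(10, 180)
#' length(unlist(plan$angles))  # 1800 projections
#' plan$spacing_deg             # 0.2 degrees when equiangular
#' @export
build_scan_plan <- function(n_subscans, n_per_subscan,
                            subscan_shift_deg = NULL,
                            reference_angle_deg = 0) {
  n_subscans <- as.integer(n_subscans)
  n_per_subscan <- as.integer(n_per_subscan)
  if (is.na(n_subscans) || is.na(n_per_subscan) || n_subscans < 1L ||
      n_per_subscan < 1L) {
    stopf("counts must be positive integers")
  }
  if (is.null(subscan_shift_deg)) {
    subscan_shift_deg <- 360 / (n_per_subscan * n_subscans)
  }
  angles <- lapply(seq_len(n_subscans) - 1L, function(k) {
    (subscan_shift_deg * k +
       360 * (seq_len(n_per_subscan) - 1L) / n_per_subscan) %% 360
  })
  merged <- sort(unlist(angles))
  gaps <- diff(merged)
  equiangular <- length(gaps) == 0L ||
    (max(gaps) - min(gaps)) < 1e-9
  structure(list(n_subscans = n_subscans, n_per_subscan = n_per_subscan,
                 subscan_shift_deg = subscan_shift_deg,
                 reference_angle_deg = reference_angle_deg %% 360,
                 angles = angles, equiangular = equiangular,
                 spacing_deg = if (equiangular && length(gaps) > 0L) {
                   mean(gaps)
                 } else {
                   NA_real_
                 }),
            class = "dvct_scan_plan")
}

check_scan_plan <- function(plan) {
  if (!inherits(plan, "dvct_scan_plan")) {
    stopf("plan must come from build_scan_plan()")
  }
  plan
}

# per-frame annotation in acquisition order: each sub-scan opens with its
# reference exposure, followed by its angular projections
scan_plan_annotation <- function(plan) {
  angles <- numeric(0)
  subscan <- integer(0)
  is_ref <- logical(0)
  for (k in seq_len(plan$n_subscans)) {
    angles <- c(angles, plan$reference_angle_deg, plan$angles[[k]])
    subscan <- c(subscan, rep(k, plan$n_per_subscan + 1L))
    is_ref <- c(is_ref, TRUE, rep(FALSE, plan$n_per_subscan))
  }
  list(angles_deg = angles, subscan_index = subscan, is_reference = is_ref)
}

#' @export
print.dvct_scan_plan <- function(x, ...) {
  cat(sprintf(
    "dvct_scan_plan: %d sub-scan(s) x %d projections (+1 reference each), shift %.4g deg, %s\n",
    x$n_subscans, x$n_per_subscan, x$subscan_shift_deg,
    if (x$equiangular) sprintf("equiangular (%.4g deg)", x$spacing_deg)
    else "not equiangular"))
  invisible(x)
}

#' Flat-field correct a projection frame
#'
#' `corrected = (raw - dark) / (open_beam - dark)`. Pixels where the
#' denominator is not positive are flagged bad; bad pixels (including any
#' supplied detector bad-pixel mask) are replaced by the median of their
#' valid 8-neighbors.
#'
#' @param raw,open_beam,dark numeric matrices of identical shape.
#' @param bad_pixel_mask optional logical matrix of known defective pixels.
#' @return corrected matrix.
#' @export
flat_field_correct <- function(raw, open_beam, dark, bad_pixel_mask = NULL) {
  if (!identical(dim(raw), dim(open_beam)) ||
      !identical(dim(raw), dim(dark))) {
    stopf("raw, open_beam and dark must have identical shapes")
  }
  denom <- open_beam - dark
  bad <- denom <= 0
  if (!is.null(bad_pixel_mask)) {
    if (!identical(dim(bad_pixel_mask), dim(raw))) {
      stopf("bad_pixel_mask shape mismatch")
    }
    bad <- bad | bad_pixel_mask
  }
  if (all(bad)) stopf("fully bad frame: no valid pixels to correct with")
  out <- matrix(0, nrow(raw), ncol(raw))
  out[!bad] <- (raw[!bad] - dark[!bad]) / denom[!bad]
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    nr <- nrow(raw)
    nc <- ncol(raw)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]
      cc <- idx[i, 2]
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, cc - 1):min(nc, cc + 1)
      nb <- out[rs, cs][!bad[rs, cs]]
      out[r, cc] <- if (length(nb)) median(nb) else NA_real_
    }
  }
  out
}

# Sub-pixel offset of a 2D correlation peak: least-squares quadratic on the
# 3x3 neighborhood (orthogonal-polynomial closed form), applied to the log
# of the NCC map when positive (a Gaussian peak model). Handles diagonally
# oriented ridges that defeat separate 1D axis fits. Returns c(dr, dc)
# relative to the integer peak, clamped to one pixel.
subpixel_peak_2d <- function(cc, peak) {
  p1 <- peak[1L]
  p2 <- peak[2L]
  if (p1 <= 1L || p2 <= 1L || p1 >= nrow(cc) || p2 >= ncol(cc)) {
    return(c(0, 0))
  }
  vals <- cc[(p1 - 1L):(p1 + 1L), (p2 - 1L):(p2 + 1L)]
  if (any(!is.finite(vals))) return(c(0, 0))
  l <- if (all(vals > 0)) log(vals) else vals
  x <- matrix(rep(-1:1, 3), 3, 3)        # dr
  y <- t(x)                              # dc
  b <- sum(x * l) / 6
  cc1 <- sum(y * l) / 6
  d <- sum((x^2 - 2 / 3) * l) / 2
  e <- sum((y^2 - 2 / 3) * l) / 2
  f <- sum(x * y * l) / 4
  hess <- matrix(c(2 * d, f, f, 2 * e), 2, 2)
  if (d >= 0 || e >= 0 || det(hess) <= 0) return(c(0, 0))
  v <- solve(hess, -c(b, cc1))
  pmin(pmax(v, -1), 1)
}

#' Estimate focal-spot drift from reference exposures
#'
#' Each reference frame is correlated against the first one (which defines
#' the zero-drift datum) by normalized cross-correlation over integer shifts
#' with quadratic 3x3 sub-pixel peak interpolation. Sub-scan `k`'s endpoint
#' shifts are the `k`-th and `(k+1)`-th reference shifts; the last sub-scan
#' extrapolates its own trend. Per-frame shifts follow by linear
#' interpolation over the acquisition index.
#'
#' @param series a [projection_series()] with at least two reference frames.
#' @param search_radius integer search bound, pixels.
#' @param min_peak minimum acceptable NCC peak; below it the estimation
#'   errors out.
#' @return a `dvct_drift_estimate`: `reference_shifts` (one row per
#'   reference), `subscan_start`, `subscan_end`, and `per_frame` (one row per
#'   frame of `series`), all `(row, col)` pixel shifts.
#' @export
estimate_reference_shifts <- function(series, search_radius = 10,
                                      min_peak = 0.3) {
  if (!inherits(series, "dvct_projections")) {
    stopf("series must be a dvct_projections")
  }
  ref_idx <- which(series$is_reference)
  if (length(ref_idx) < 2L) stopf("need at least 2 reference frames")
  ref0 <- series$frames[[ref_idx[1L]]]
  nref <- length(ref_idx)
  shifts <- matrix(0, nref, 2)
  margin <- search_radius + 2L
  for (i in seq_len(nref)[-1L]) {
    cc <- cpp_xcorr2(ref0, series$frames[[ref_idx[i]]], search_radius,
                     margin)
    if (all(is.na(cc))) stopf("reference correlation failed (flat frames?)")
    peak <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    if (cc[peak[1L], peak[2L]] < min_peak) {
      stopf("correlation peak %.3f below threshold %.3f",
            cc[peak[1L], peak[2L]], min_peak)
    }
    intshift <- peak - (search_radius + 1L)
    shifts[i, ] <- if (cc[peak[1L], peak[2L]] < 1 - 1e-12) {
      # sub-pixel step: quadratic seed on the NCC map, then a 2D
      # translation-only Lucas-Kanade refinement run in the
      # forward-synthesis direction (the pristine first reference is
      # warped to match the drifted frame, avoiding resampling bias)
      seed <- intshift + subpixel_peak_2d(cc, peak)
      -cpp_lk2d(series$frames[[ref_idx[i]]], ref0, margin, -seed, 1e-4,
                50L)
    } else {
      intshift  # perfect integer match needs no refinement
    }
  }
  n_sub <- max(series$subscan_index)
  if (nref != n_sub) {
    stopf("expected one reference frame per sub-scan (%d vs %d)", nref,
          n_sub)
  }
  start <- shifts
  end <- rbind(shifts[-1L, , drop = FALSE],
               shifts[nref, ] + (shifts[nref, ] - shifts[nref - 1L, ]))
  # frames per sub-scan including the reference exposure
  npg <- sum(series$subscan_index == series$subscan_index[1L])
  per_frame <- matrix(0, length(series$frames), 2)
  pos <- 0L
  for (k in seq_len(n_sub)) {
    nk <- sum(series$subscan_index == k)
    frac <- (seq_len(nk) - 1L) / npg  # next reference sits npg slots on
    per_frame[pos + seq_len(nk), ] <-
      cbind(start[k, 1] + frac * (end[k, 1] - start[k, 1]),
            start[k, 2] + frac * (end[k, 2] - start[k, 2]))
    pos <- pos + nk
  }
  structure(list(reference_shifts = shifts, subscan_start = start,
                 subscan_end = end, per_frame = per_frame),
            class = "dvct_drift_estimate")
}

#' Compensate focal-spot drift in a projection series
#'
#' Every frame is translated by minus its interpolated drift (sub-pixel via
#' bilinear interpolation); reference frames are dropped from the returned
#' science set.
#'
#' @param series a [projection_series()].
#' @param est a drift estimate from [estimate_reference_shifts()] covering
#'   every frame.
#' @param fill value for pixels shifted in from outside the detector.
#' @return the corrected [projection_series()] without reference frames.
#' @export
correct_drift <- function(series, est, fill = 0) {
  if (!inherits(series, "dvct_projections")) {
    stopf("series must be a dvct_projections")
  }
  if (!inherits(est, "dvct_drift_estimate")) {
    stopf("est must come from estimate_reference_shifts()")
  }
  if (nrow(est$per_frame) != length(series$frames)) {
    stopf("drift estimate covers %d frames but series has %d",
          nrow(est$per_frame), length(series$frames))
  }
  keep <- which(!series$is_reference)
  frames <- lapply(keep, function(f) {
    cpp_shift2d(series$frames[[f]], -est$per_frame[f, 1],
                -est$per_frame[f, 2], fill)
  })
  projection_series(frames, series$angles_deg[keep],
                    series$subscan_index[keep],
                    rep(FALSE, length(keep)))
}
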