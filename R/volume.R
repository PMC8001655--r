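#' Construct a 3D intensity volume
#'
#' The container every registration, blending and DVC operation works on: a
#' 3D scalar grid with a physical voxel size. Axis order is `(z, y, x)` with
#' `z` the axial (slice) direction; element `data[z, y, x]` is the voxel at
#' 1-based index `(z, y, x)`, whose center sits at physical position
#' `origin + (index - 1) * voxel_size` (micrometres).
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`, all `>= 1`.
#' @param voxel_size voxel edge length(s) in micrometres; scalar or length-3
#'   `(z, y, x)`, all `> 0`.
#' @param origin physical coordinate of the center of voxel `(1, 1, 1)` in
#'   micrometres; scalar or length-3.
#' @return An object of class `dvct_volume` with fields `data`, `voxel_size`,
#'   `origin`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), voxel_size = 2)
#' dim(v$data)
#' @export
volume <- function(data, voxel_size = 1, origin = 0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("volume data must be a 3D array (z, y, x)")
  }
  if (any(dim(data) < 1L)) stopf("all three dimensions must be >= 1")
  voxel_size <- as_len3(voxel_size, "voxel_size")
  if (any(voxel_size <= 0)) stopf("voxel_size must be > 0 on every axis")
  origin <- as_len3(origin, "origin")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "dvct_volume")
}

#' @export
print.dvct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "dvct_volume: %d x %d x %d voxels (z, y, x), voxel size %s um\n",
    d[1], d[2], d[3], paste(format(x$voxel_size), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.dvct_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "dvct_volume")

check_volume <- function(v, what = "volume") {
  if (!is_volume(v)) stopf("%s must be a dvct_volume (see volume())", what)
  v
}

#' Construct a projection series
#'
#' An ordered stack of 2D radiographs with per-frame rotation angle, sub-scan
#' index and a flag marking the repeated fixed-angle reference exposures used
#' for focal-spot drift estimation. Frame matrices are `(detector row, column)`
#' with rows parallel to the rotation axis.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param angles_deg rotation angle per frame, degrees.
#' @param subscan_index 1-based sub-scan index per frame.
#' @param is_reference logical per frame.
#' @return An object of class `dvct_projections`.
#' @export
projection_series <- function(frames, angles_deg, subscan_index,
                              is_reference) {
  n <- length(frames)
  if (length(angles_deg) != n || length(subscan_index) != n ||
      length(is_reference) != n) {
    stopf("angles_deg, subscan_index and is_reference need one entry per frame")
  }
  if (n > 0L) {
    shp <- dim(frames[[1L]])
    ok <- vapply(frames, function(f) {
      is.matrix(f) && identical(dim(f), shp)
    }, logical(1L))
    if (!all(ok)) stopf("all frames must be matrices of identical shape")
  }
  for (k in unique(subscan_index)) {
    a <- angles_deg[subscan_index == k & !is_reference]
    if (length(a) > 1L && any(diff(a) <= 0)) {
      stopf("non-reference angles must be strictly increasing within sub-scan %d", k)
    }
  }
  structure(list(frames = frames, angles_deg = as.numeric(angles_deg),
                 subscan_index = as.integer(subscan_index),
                 is_reference = as.logical(is_reference)),
            class = "dvct_projections")
}

#' @export
print.dvct_projections <- function(x, ...) {
  cat(sprintf("dvct_projections: %d frames (%d reference), %d sub-scan(s)\n",
              length(x$frames), sum(x$is_reference),
              length(unique(x$subscan_index))))
  invisible(x)
}
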