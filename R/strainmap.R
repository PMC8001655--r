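# Nodal displacements -> per-cell deformation gradient -> Green-Lagrange
# strain. The per-cell affine is fitted by least squares to the 8 (or, for
# planar node grids, 4) nodes constituting the cell, matching the per-voxel
# affine construction of the DVC pipeline; E = (F^T F - I) / 2 is invariant
# under rigid rotation, so rigid motion maps to zero strain.

#' Nodal displacements from coordinate pairs
#'
#' @param ref_coords,def_coords `n x 3` node coordinate matrices (deformed
#'   minus reference).
#' @return `n x 3` displacement matrix.
#' @export
nodal_displacements <- function(ref_coords, def_coords) {
  r <- as.matrix(ref_coords)
  q <- as.matrix(def_coords)
  if (!identical(dim(r), dim(q))) stopf("node counts must match")
  q - r
}

#' Least-squares affine of one cell
#'
#' Fits the affine map taking the cell's reference corner positions to their
#' displaced positions; exact whenever the corner displacements are
#' affine-consistent. The linear part is the cell's deformation gradient.
#'
#' @param node_positions `k x 3` reference corner coordinates (k >= 4,
#'   non-degenerate).
#' @param node_displacements `k x 3` corner displacements.
#' @return an [affine_transform()].
#' @export
voxel_affine <- function(node_positions, node_displacements) {
  p <- as.matrix(node_positions)
  u <- as.matrix(node_displacements)
  if (!identical(dim(p), dim(u)) || ncol(p) != 3L || nrow(p) < 4L) {
    stopf("need matching k x 3 positions and displacements, k >= 4")
  }
  x <- cbind(p, 1)
  if (qr(x)$rank < 4L) stopf("degenerate corner set")
  b <- solve(crossprod(x), crossprod(x, p + u))  # 4 x 3
  affine_transform(t(b[1:3, ]), b[4L, ], "general")
}

#' Green-Lagrange strain tensor
#'
#' `E = (F^T F - I) / 2` for a deformation gradient `F`; symmetric, zero for
#' any pure rotation.
#'
#' @param f 3x3 deformation gradient.
#' @return symmetric 3x3 strain tensor.
#' @export
green_lagrange <- function(f) {
  f <- as.matrix(f)
  if (!identical(dim(f), c(3L, 3L)) || !all(is.finite(f))) {
    stopf("F must be a finite 3x3 matrix")
  }
  e <- (crossprod(f) - diag(3)) / 2
  (e + t(e)) / 2  # enforce exact symmetry
}

# least-squares 2x2 affine of a planar 4-node cell in the given axes
cell_affine_2d <- function(p2, u2) {
  x <- cbind(p2, 1)
  b <- solve(crossprod(x), crossprod(x, p2 + u2))
  t(b[1:2, ])
}

#' Per-cell strain field from a displacement field
#'
#' Walks the node lattice of a filtered [displacement_field()] cell by cell;
#' each cell's deformation gradient comes from the least-squares affine of
#' its corner nodes and its Green-Lagrange tensor follows. Planar fields
#' (single-layer lattice) yield the in-plane deformation gradient embedded
#' in identity: the out-of-plane gradient components are unobservable from
#' one plane and are taken as zero.
#'
#' @param f a [displacement_field()] with no unconverged nodes (run
#'   [filter_field()] first).
#' @return a `dvct_strain` data.frame: cell-center coordinates, the 9
#'   deformation-gradient entries `F11..F33` and the 6 strain components
#'   `E11, E22, E33, E12, E13, E23` (axes 1 = z, 2 = y, 3 = x).
#' @export
strain_field <- function(f) {
  if (!inherits(f, "dvct_field")) stopf("f must be a displacement field")
  if (any(f$status == "unconverged")) {
    stopf("field contains unconverged nodes; run filter_field() first")
  }
  key <- paste(f$gi, f$gj, f$gk)
  row_of <- stats::setNames(seq_len(nrow(f)), key)
  planar <- length(unique(f$gk)) == 1L
  gis <- sort(unique(f$gi))
  gjs <- sort(unique(f$gj))
  gks <- sort(unique(f$gk))
  out <- list()
  corner_rows <- function(ci, cj, ck) {
    ks <- as.vector(outer(
      as.vector(outer(ci, cj, function(a, b) paste(a, b))), ck, paste))
    r <- row_of[ks]
    if (anyNA(r)) NULL else as.integer(r)
  }
  push <- function(rows) {
    p <- as.matrix(f[rows, c("z", "y", "x")])
    u <- as.matrix(f[rows, c("uz", "uy", "ux")])
    fmat <- if (length(rows) == 8L) {
      voxel_affine(p, u)$linear
    } else {
      # planar cell: fit in the two varying axes, embed in identity
      varying <- which(apply(p, 2, function(cc) length(unique(cc)) > 1L))
      if (length(varying) != 2L) return(NULL)
      f2 <- cell_affine_2d(p[, varying], u[, varying])
      fm <- diag(3)
      fm[varying, varying] <- f2
      fm
    }
    if (is.null(fmat)) return(NULL)
    e <- green_lagrange(fmat)
    c(colMeans(p), as.vector(t(fmat)),
      e[1, 1], e[2, 2], e[3, 3], e[1, 2], e[1, 3], e[2, 3])
  }
  for (ck_i in seq_len(max(1L, length(gks) - 1L))) {
    ck <- if (planar) gks[1L] else gks[ck_i + c(0L, 1L)]
    if (!planar && ck_i >= length(gks)) break
    for (cj_i in seq_len(length(gjs) - 1L)) {
      for (ci_i in seq_len(length(gis) - 1L)) {
        rows <- corner_rows(gis[ci_i + c(0L, 1L)], gjs[cj_i + c(0L, 1L)],
                            ck)
        if (is.null(rows)) next
        rec <- push(rows)
        if (!is.null(rec)) out[[length(out) + 1L]] <- rec
      }
    }
    if (planar) break
  }
  if (length(out) == 0L) stopf("lattice has no complete cells")
  m <- do.call(rbind, out)
  colnames(m) <- c("z", "y", "x", paste0("F", as.vector(t(outer(1:3, 1:3,
                                                                paste0)))),
                   "E11", "E22", "E33", "E12", "E13", "E23")
  structure(as.data.frame(m), class = c("dvct_strain", "data.frame"))
}
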