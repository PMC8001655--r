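# shared fixtures and independent oracles, built in code at test time

# smooth speckle-textured volume (no canals) for correlation tests
textured_volume <- function(shape = c(48, 48, 48), seed = 7,
                            amplitude = 0.15, level = 200, sigma = 1.5,
                            voxel_size = 2) {
  set.seed(seed)
  field <- array(stats::rnorm(prod(shape)), shape)
  sm <- dvctomo:::cpp_gaussian_smooth3(field, sigma)
  volume(level * (1 + amplitude * sm / stats::sd(sm)),
         voxel_size = voxel_size)
}

# window voxel index ranges matching the engine's half-open convention
win_range <- function(center, w) {
  lo <- -((w - 1) %/% 2)
  center + seq(lo, lo + w - 1)
}

# independent exhaustive integer-search oracle: plain Pearson correlation of
# extracted windows over the full displacement cube
ncc_oracle <- function(ref, def, node, w, radius) {
  a <- as.vector(ref$data[win_range(node[1], w), win_range(node[2], w),
                          win_range(node[3], w)])
  best <- -Inf
  best_d <- c(0, 0, 0)
  for (dz in -radius:radius) for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      b <- as.vector(def$data[win_range(node[1] + dz, w),
                              win_range(node[2] + dy, w),
                              win_range(node[3] + dx, w)])
      r <- suppressWarnings(stats::cor(a, b))
      if (is.finite(r) && r > best) {
        best <- r
        best_d <- c(dz, dy, dx)
      }
    }
  }
  list(disp = best_d, ncc = best)
}

# sub-pixel 2D shift of `img` relative to `ref` (NCC + quadratic peak fit);
# independent of the drift-estimation code path only in its use here as a
# measurement device on known constructions
measure_frame_shift <- function(ref, img, radius = 6) {
  cc <- dvctomo:::cpp_xcorr2(ref, img, radius, radius + 2)
  peak <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  intshift <- unname(peak - (radius + 1))
  if (cc[peak[1], peak[2]] >= 1 - 1e-12) return(intshift)
  seed <- intshift + dvctomo:::subpixel_peak_2d(cc, peak)
  -as.numeric(dvctomo:::cpp_lk2d(img, ref, radius + 2, -seed, 1e-4, 50L))
}

# lattice displacement field from an analytic displacement function
# u_fun(z, y, x) -> c(uz, uy, ux); nodes on a full 3D lattice
analytic_field <- function(zs, ys, xs, u_fun) {
  g <- expand.grid(gi = seq_along(zs), gj = seq_along(ys),
                   gk = seq_along(xs))
  nodes <- cbind(zs[g$gi], ys[g$gj], xs[g$gk])
  u <- t(apply(nodes, 1, function(p) u_fun(p[1], p[2], p[3])))
  displacement_field(nodes, u, rep(1, nrow(nodes)),
                     rep("converged", nrow(nodes)), as.matrix(g))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# dilate a logical mask by one voxel (26-neighborhood), used to ignore the
# interpolation boundary around ground-truth cracks
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    zs <- pmin(pmax(seq_len(d[1]) + dz, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    xs <- pmin(pmax(seq_len(d[3]) + dx, 1), d[3])
    out <- out | mask[zs, ys, xs]
  }
  out
}
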