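gauss_dip_profile <- function(sigma_um, step = 0.05, half_span = 25,
                              depth = 100, base = 200) {
  pos <- seq(0, 2 * half_span, by = step)
  ints <- base - depth * exp(-0.5 * ((pos - half_span) / sigma_um)^2)
  structure(list(positions = pos, intensities = ints, step = step),
            class = "dvct_profile")
}

test_that("profile extraction samples the interpolated segment", {
  v <- volume(array(7, c(10, 10, 10)), voxel_size = 2)
  p <- extract_profile(v, c(4, 4, 4), c(4, 4, 16), step = 1)
  expect_true(all(p$intensities == 7))
  expect_equal(max(p$positions), 12)
  # axis-aligned segment at integer voxel coordinates gives exact values
  v2 <- textured_volume(c(12, 12, 12), seed = 3)
  p2 <- extract_profile(v2, c(10, 10, 2), c(10, 10, 18), step = 2)
  expect_equal(p2$intensities, v2$data[6, 6, 2:10])
  expect_error(extract_profile(v, c(4, 4, 4), c(4, 4, 40)), "domain")
  # 2D slice input with bilinear sampling
  m <- matrix(3, 9, 9)
  p3 <- extract_profile(m, c(2, 1), c(2, 7), step = 0.5, pixel_size = 1)
  expect_true(all(p3$intensities == 3))
})

test_that("FWHM closed forms: Gaussian and rectangular dips", {
  # Gaussian dip, sigma = 2 um -> FWHM = 2 sqrt(2 ln 2) * 2
  p <- gauss_dip_profile(2)
  res <- fwhm(p, "dip")
  expect_equal(res$width, 2 * sqrt(2 * log(2)) * 2, tolerance = p$step)
  # rectangular dip of width w on a flat baseline
  pos <- seq(0, 30, by = 0.1)
  ints <- ifelse(pos >= 12 & pos < 18, 50, 200)
  pr <- list(positions = pos, intensities = ints)
  expect_equal(fwhm(pr, "dip")$width, 6, tolerance = 0.1)
  # peaks work symmetrically
  pk <- list(positions = pos, intensities = 400 - ints)
  expect_equal(fwhm(pk, "peak")$width, 6, tolerance = 0.1)
})

test_that("FWHM of CT-width and SEM-width profiles gives the 2.425 ratio", {
  to_sigma <- function(fwhm_um) fwhm_um / (2 * sqrt(2 * log(2)))
  ct <- fwhm(gauss_dip_profile(to_sigma(9.7)), "dip")
  sem <- fwhm(gauss_dip_profile(to_sigma(4)), "dip")
  expect_equal(ct$width / sem$width, 9.7 / 4, tolerance = 0.02)
  expect_equal(round(9.7 / 4, 3), 2.425)
})

test_that("FWHM invariances and error contracts", {
  p <- gauss_dip_profile(3)
  w0 <- fwhm(p, "dip")$width
  # affine intensity rescaling a*I + b, a > 0
  p2 <- p
  p2$intensities <- 3.7 * p$intensities + 55
  expect_equal(fwhm(p2, "dip")$width, w0, tolerance = 1e-9)
  # profile reversal
  p3 <- p
  p3$intensities <- rev(p$intensities)
  expect_equal(fwhm(p3, "dip")$width, w0, tolerance = 1e-9)
  # no crossing: monotone profile
  mono <- list(positions = 1:20, intensities = 20:1)
  expect_error(fwhm(mono, "dip"), "crossing|extrema")
  # two separated equal minima
  twin <- list(positions = seq(0, 10, 0.5),
               intensities = c(rep(10, 5), 1, rep(10, 9), 1, rep(10, 5)))
  expect_error(fwhm(twin, "dip"), "multiple")
})

test_that("void segmentation recovers an internal crack, drops surface", {
  ph <- make_bone_phantom(phantom_spec(shape = c(48, 64, 64),
                                       canal_count = 0,
                                       texture_amplitude = 0.08,
                                       seed = 19))
  crk <- crack_spec(center = c(24, 32, 32), normal = c(1, 0, 0),
                    half_extent = 24, width = 6)
  ins <- insert_crack(ph, crk)
  seg <- segment_voids(ins$volume, threshold = "otsu",
                       exclusion_margin = 8)
  dice <- 2 * sum(seg & ins$mask) / (sum(seg) + sum(ins$mask))
  expect_gte(dice, 0.95)
  # crack-free phantom segments to nothing (air shell is excluded)
  seg0 <- segment_voids(ph$volume, threshold = "otsu",
                        exclusion_margin = 8)
  expect_equal(sum(seg0), 0)
  # surface-connected void is excluded
  open_v <- ph$volume
  open_v$data[20:28, 1:32, 30:34] <- ph$spec$void_level
  seg1 <- segment_voids(open_v, threshold = "otsu", exclusion_margin = 8)
  expect_equal(sum(seg1[20:28, 1:32, 30:34]), 0)
  expect_error(segment_voids(volume(array(5, c(8, 8, 8)), voxel_size = 2)),
               "constant")
})

test_that("crack measurement: slab width and disc length oracles", {
  d <- c(40, 60, 60)
  vox <- 2
  # planar disc crack: width 10 um (5 layers), diameter 80 um
  mask <- array(FALSE, d)
  yy <- matrix(seq_len(d[2]), d[2], d[3])
  xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  disc <- (yy - 30)^2 + (xx - 30)^2 <= 20^2
  for (z in 18:22) mask[z, , ][disc] <- TRUE
  m <- measure_crack(mask, vox)
  expect_equal(m$width, 10, tolerance = vox)
  expect_equal(m$length, 80, tolerance = 0.05 * 80)
  # single voxel: width one voxel, length zero
  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  ms <- measure_crack(single, 2)
  expect_equal(ms$width, 2)
  expect_equal(ms$length, 0)
  # length invariant under axis-aligned 90-degree rotation
  rot <- aperm(mask, c(1, 3, 2))[, , seq(d[3], 1)]
  mr <- measure_crack(rot, vox)
  expect_equal(mr$length, m$length, tolerance = 1e-9)
  expect_error(measure_crack(array(FALSE, c(4, 4, 4)), 2), "empty")
  two <- single
  two[1, 1, 1] <- TRUE
  expect_error(measure_crack(two, 2), "connected")
})

test_that("measured width grows monotonically with phantom crack width", {
  ph <- make_bone_phantom(phantom_spec(shape = c(40, 56, 56),
                                       canal_count = 0,
                                       texture_amplitude = 0, seed = 2))
  widths <- c(4, 8, 12, 16, 20)
  got <- vapply(widths, function(w) {
    ins <- insert_crack(ph, crack_spec(c(20, 28, 28), c(1, 0, 0),
                                       half_extent = 20, width = w))
    measure_crack(ins$mask, ph$spec$voxel_size)$width
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
  expect_equal(got, widths, tolerance = 2)
})
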