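test_that("support-point grid contract", {
  v <- textured_volume(c(40, 40, 40), seed = 3)
  pts <- pick_support_points(v, crack_tip = c(20, 12, 20), standoff = 10,
                             direction = c(0, 1, 0))
  expect_equal(nrow(pts), 125L)
  expect_equal(nrow(unique(pts)), 125L)
  expect_true(all(pts >= 1) && all(pts <= 40))
  # grid intersecting a supplied void mask is an error
  void <- array(FALSE, c(40, 40, 40))
  void[, 18:26, ] <- TRUE
  expect_error(pick_support_points(v, c(20, 12, 20), standoff = 10,
                                   direction = c(0, 1, 0),
                                   void_mask = void),
               "void")
  expect_error(pick_support_points(v, c(20, 36, 20), standoff = 10,
                                   direction = c(0, 1, 0)),
               "leaves the volume")
})

test_that("transform fitting: exact recovery, kinds agree on rigid motion", {
  set.seed(7)
  pts <- matrix(runif(3 * 40, 0, 50), 40, 3)
  # pure translation: identity linear part for both kinds
  for (kind in c("general", "rigid")) {
    tr <- fit_transform(pts, sweep(pts, 2, c(1.5, -2, 3), `+`),
                        kind = kind)
    expect_equal(tr$linear, diag(3), tolerance = 1e-9)
    expect_equal(tr$translation, c(1.5, -2, 3), tolerance = 1e-9)
  }
  # noise-free rotation + translation: exact recovery, and the general fit
  # reproduces the rigid one
  rot <- rotation_z(17)
  t0 <- c(2, -1, 0.5)
  def <- t(rot %*% t(pts)) + matrix(t0, 40, 3, byrow = TRUE)
  fr <- fit_transform(pts, def, kind = "rigid")
  fg <- fit_transform(pts, def, kind = "general")
  expect_equal(fr$linear, rot, tolerance = 1e-9)
  expect_equal(fr$translation, t0, tolerance = 1e-9)
  expect_equal(fg$linear, fr$linear, tolerance = 1e-9)
  expect_equal(fg$translation, fr$translation, tolerance = 1e-9)
  # weights: a corrupted zero-weight point does not perturb the fit
  def2 <- def
  def2[1, ] <- def2[1, ] + 40
  w <- c(0, rep(1, 39))
  fw <- fit_transform(pts, def2, weights = w, kind = "rigid")
  expect_equal(fw$linear, rot, tolerance = 1e-9)
  # degenerate geometry
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_transform(line, line, kind = "rigid"), "collinear")
  plane <- cbind(runif(10), runif(10), 1)
  expect_error(fit_transform(plane, plane, kind = "general"), "coplanar")
})

test_that("resampling: identity, integer shift, approximate inverse", {
  ph <- make_bone_phantom(phantom_spec(shape = c(48, 48, 48),
                                       canal_count = 2, canal_radius = 6,
                                       seed = 9))
  v <- ph$volume
  ident <- resample_volume(v, affine_transform(diag(3), c(0, 0, 0)))
  expect_equal(ident$data, v$data)
  sh <- resample_volume(v, affine_transform(diag(3), c(0, 2, 0)))
  expect_equal(sh$data[, 1:44, ], v$data[, 3:46, ])
  # resample by t then t^-1 on the phantom: RMS error over interior tissue
  # (interfaces excluded - partial-volume voxels dominate otherwise) stays
  # below 1.5% of dynamic range; the floor is set by double trilinear
  # smoothing of the speckle texture, measured at ~1.3%
  rot <- rotation_z(5)
  tr <- affine_transform(rot, c(0.4, -0.6, 0.2))
  inv <- affine_transform(solve(rot),
                          as.numeric(-solve(rot) %*% tr$translation))
  back <- resample_volume(resample_volume(v, tr), inv)
  core <- array(FALSE, dim(v$data))
  core[13:36, 13:36, 13:36] <- TRUE
  sel <- core & !dilate1(dilate1(!ph$tissue_mask))
  rmsd <- sqrt(mean((back$data[sel] - v$data[sel])^2))
  expect_lt(rmsd, 0.015 * diff(range(v$data)))
})

test_that("blending is the exact linear formula", {
  a <- volume(array(10, c(4, 4, 4)), voxel_size = 2)
  b <- volume(array(1, c(4, 4, 4)), voxel_size = 2)
  expect_equal(blend(a, b, 20)$data, array(30, c(4, 4, 4)))
  z <- volume(array(0, c(4, 4, 4)), voxel_size = 2)
  expect_equal(blend(a, z, 37)$data, a$data)
  v <- textured_volume(c(8, 8, 8), seed = 1)
  expect_equal(blend(v, v, 7)$data, 8 * v$data)
  # integer inputs stay exact
  ai <- volume(array(sample(0:255, 64, TRUE), c(4, 4, 4)), voxel_size = 2)
  bi <- volume(array(sample(0:255, 64, TRUE), c(4, 4, 4)), voxel_size = 2)
  expect_true(all(blend(ai, bi, 20)$data == ai$data + 20 * bi$data))
  expect_error(blend(a, volume(array(1, c(4, 4, 5)), voxel_size = 2), 2),
               "shape")
})

test_that("multiplier selection maximizes a computable CNR", {
  set.seed(21)
  d <- c(20, 20, 20)
  tissue <- array(FALSE, d)
  tissue[, 1:10, ] <- TRUE
  void <- !tissue
  # two-level volumes with known means and variances
  vr <- volume(array(0, d), voxel_size = 2)
  vr$data[tissue] <- 200
  vr$data[void] <- 20
  vl <- vr
  noise <- array(rnorm(prod(d), sd = 5), d)
  vrn <- volume(vr$data + noise, voxel_size = 2)
  vln <- volume(vl$data + array(rnorm(prod(d), sd = 5), d),
                voxel_size = 2)
  sel <- select_multiplier(vrn, vln, void, tissue, m_range = c(2, 10, 20))
  # independent closed-form oracle for the same three m values
  oracle <- vapply(c(2, 10, 20), function(m) {
    vb <- vrn$data + m * vln$data
    tv <- vb[tissue]
    vv <- vb[void]
    pooled <- sqrt(((length(tv) - 1) * var(tv) + (length(vv) - 1) *
                      var(vv)) / (length(tv) + length(vv) - 2))
    abs(mean(tv) - mean(vv)) / pooled
  }, numeric(1))
  expect_equal(sel$curve$cnr, oracle, tolerance = 1e-12)
  expect_true(sel$m %in% c(2, 10, 20))
  # identical masked populations -> CNR 0 everywhere (two halves of a
  # constant region)
  h1 <- tissue
  h1[, , 11:20] <- FALSE
  h2 <- tissue & !h1
  vflat <- volume(array(100, d), voxel_size = 2)
  flat <- select_multiplier(vflat, vflat, h1, h2, m_range = 2:4)
  expect_equal(flat$curve$cnr, rep(0, 3))
  # returned m always within the requested range
  expect_true(sel$m >= 2 && sel$m <= 50)
  expect_error(select_multiplier(vrn, vln, void & FALSE, tissue), "empty")
})

test_that("end-to-end: blending reveals a new crack after local alignment", {
  ph <- make_bone_phantom(phantom_spec(shape = c(80, 80, 80),
                                       canal_count = 2, canal_radius = 6,
                                       seed = 33))
  # loaded state: rigid sub-voxel move of the reference plus a new crack
  move <- affine_transform(diag(3), c(1.3, -0.7, 0.4))
  loaded <- apply_deformation(ph$volume, move)
  crk <- crack_spec(center = c(40, 40, 40), normal = c(1, 0.15, 0),
                    half_extent = c(28, 20), width = 8)
  ins <- insert_crack(volume(loaded$data, voxel_size = 2), crk,
                      void_level = ph$spec$void_level,
                      tissue_mask = ph$tissue_mask)
  # the phantom is noise-free, so the prefilter stays off (kernel 1)
  cfg <- correlation_config(window_size = 12, prefilter_kernel = 1,
                            search_radius = 4)
  reg <- register_local(ph$volume, ins$volume, crack_tip = c(40, 40, 55),
                        standoff = 8, direction = c(0, 0, 1),
                        kind = "general", cfg = cfg, min_ncc = 0.9)
  # recovered transform matches the prescribed rigid move where it is
  # used: at the support-point centroid (the affine's translation alone
  # extrapolates the small linear-part noise all the way to the origin)
  ctr <- colMeans(reg$points) - 1
  pred <- as.numeric(reg$transform$linear %*% ctr +
                       reg$transform$translation)
  expect_lt(max(abs(pred - (ctr + move$translation))), 0.05)
  expect_lt(max(abs(reg$transform$linear - diag(3))), 0.005)
  aligned <- resample_volume(ins$volume, reg$transform)
  vb <- blend(ph$volume, aligned, m = 20)
  thr <- otsu_threshold(vb$data)
  below <- vb$data < thr
  # the crack mask mapped back to reference coordinates (rigid move known);
  # one-voxel interface layers are partial-volume voxels and are excluded
  # from both scores, as usual in segmentation validation
  idx <- which(ins$mask, arr.ind = TRUE)
  idx_ref <- sweep(idx, 2, round(move$translation))
  keep <- idx_ref[, 1] >= 1 & idx_ref[, 2] >= 1 & idx_ref[, 3] >= 1 &
    idx_ref[, 1] <= 80 & idx_ref[, 2] <= 80 & idx_ref[, 3] <= 80
  crack_ref <- array(FALSE, c(80, 80, 80))
  crack_ref[idx_ref[keep, , drop = FALSE]] <- TRUE
  crack_interior <- crack_ref & !dilate1(!crack_ref)
  expect_gte(mean(below[crack_interior]), 0.95)
  # exclude interfaces and the volume-border slices lost to the rigid
  # motion (out-of-domain fill in the aligned volume)
  border <- array(TRUE, c(80, 80, 80))
  border[4:77, 4:77, 4:77] <- FALSE
  tissue_interior <- ph$tissue_mask & !border &
    !dilate1(dilate1(!ph$tissue_mask | crack_ref))
  expect_lte(mean(below[tissue_interior]), 0.01)
})
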