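cfg_small <- function(w = 8, ...) {
  correlation_config(window_size = w, prefilter_kernel = 1,
                     search_radius = 4, ...)
}

test_that("median prefilter basics", {
  v <- volume(array(5, c(6, 6, 6)), voxel_size = 2)
  expect_equal(prefilter(v, 1)$data, v$data)
  expect_equal(prefilter(v, 3)$data, v$data)
  imp <- v
  imp$data[3, 3, 3] <- 500
  expect_equal(prefilter(imp, 3)$data, v$data)
  expect_error(prefilter(v, 4), "odd")
})

test_that("integer search matches the exhaustive oracle", {
  v <- textured_volume(c(36, 36, 36), seed = 13)
  def <- apply_deformation(v, affine_transform(diag(3), c(2, -1, 3)))
  cfg <- cfg_small()
  # identity case
  same <- integer_search(v, v, c(18, 18, 18), cfg)
  expect_equal(same$disp, c(0, 0, 0))
  expect_equal(same$ncc, 1.0, tolerance = 1e-12)
  # 20 random nodes: hill climb == independent exhaustive oracle
  set.seed(99)
  nodes <- cbind(sample(14:22, 20, TRUE), sample(14:22, 20, TRUE),
                 sample(14:22, 20, TRUE))
  for (i in seq_len(nrow(nodes))) {
    got <- integer_search(v, def, nodes[i, ], cfg)
    oracle <- ncc_oracle(v, def, nodes[i, ], cfg$window_size,
                         cfg$search_radius)
    expect_equal(got$disp, oracle$disp)
    expect_equal(got$ncc, oracle$ncc, tolerance = 1e-9)
  }
  # zero-variance window errors
  flat <- volume(array(1, c(30, 30, 30)), voxel_size = 2)
  expect_error(integer_search(flat, flat, c(15, 15, 15), cfg),
               "zero-variance")
  expect_error(integer_search(v, def, c(2, 2, 2), cfg), "bounds")
})

test_that("sub-voxel refinement: exact on integers, <=0.05 on synthesized shifts", {
  v <- textured_volume(c(40, 40, 40), seed = 17)
  cfg <- cfg_small(w = 12)
  # def = ref: converges immediately at zero
  r0 <- subvoxel_refine(v, v, c(20, 20, 20), cfg = cfg)
  expect_equal(r0$u, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(r0$status, "converged")
  expect_lte(r0$iterations, 1L)
  # integer shifts are exact
  def_i <- apply_deformation(v, affine_transform(diag(3), c(2, -3, 1)))
  ri <- subvoxel_refine(v, def_i, c(20, 20, 20), init = c(2, -3, 1),
                        cfg = cfg)
  expect_equal(ri$u, c(2, -3, 1), tolerance = 1e-6)
  # synthesized sub-voxel shifts recovered within 0.05 voxel through the
  # two-step pipeline (with the median prefilter of the method)
  set.seed(31)
  k3 <- correlation_config(window_size = 18, prefilter_kernel = 3,
                           search_radius = 4)
  vf <- prefilter(v, 3)
  for (rep in 1:4) {
    sh <- runif(3, -1, 1)
    def <- apply_deformation(v, affine_transform(diag(3), sh))
    deff <- prefilter(def, 3)
    st <- integer_search(vf, deff, c(20, 20, 20), k3)
    r <- subvoxel_refine(vf, deff, c(20, 20, 20), init = st$disp, cfg = k3)
    expect_equal(r$status, "converged")
    expect_lt(max(abs(r$u - sh)), 0.05)
  }
})

test_that("sub-voxel refinement recovers a small affine warp", {
  v <- textured_volume(c(48, 48, 48), seed = 23)
  shear <- diag(3)
  shear[2, 3] <- 0.02  # dy/dx shear
  tr <- affine_transform(shear, as.numeric((diag(3) - shear) %*%
                                             rep(23.5, 3)))
  def <- apply_deformation(v, tr)  # warp fixed about the volume center
  cfg <- correlation_config(window_size = 18, prefilter_kernel = 1,
                            search_radius = 4)
  r <- subvoxel_refine(v, def, c(24, 24, 24), cfg = cfg)
  expect_equal(r$status, "converged")
  # recovered affine deviation within 10% of the prescribed shear
  expect_lt(abs(r$A[2, 3] - 0.02), 0.002)
  expect_lt(max(abs(r$A - (shear - diag(3)))), 0.005)
})

test_that("correlate_plane tracks a rigid shift and honors the node grid", {
  v <- textured_volume(c(40, 40, 40), seed = 29)
  cfg <- correlation_config(window_size = 8, node_offset = 6,
                            prefilter_kernel = 1, search_radius = 4)
  f0 <- correlate_plane(v, v, axis = "x", index = 20, slab_thickness = 21,
                        cfg = cfg, apply_prefilter = FALSE)
  expect_true(all(f0$status == "converged"))
  expect_equal(max(abs(as.matrix(f0[, c("uz", "uy", "ux")]))), 0,
               tolerance = 1e-9)
  # node count equals the medial-plane grid size implied by the config
  margin <- cfg$window_size %/% 2 + cfg$search_radius + 1
  per_axis <- length(seq(margin + 1, 40 - margin, by = cfg$node_offset))
  expect_equal(nrow(f0), per_axis^2)
  expect_true(all(f0$x == 20))
  # rigid (0, 4, 4) shift: all converged nodes within 0.05 voxel
  def <- apply_deformation(v, affine_transform(diag(3), c(0, 4, 4)))
  f1 <- correlate_plane(v, def, axis = "x", index = 18,
                        slab_thickness = 21, cfg = cfg,
                        apply_prefilter = FALSE)
  expect_true(all(f1$status == "converged"))
  err <- abs(sweep(as.matrix(f1[, c("uz", "uy", "ux")]), 2, c(0, 4, 4)))
  expect_lt(max(err), 0.05)
  expect_error(correlate_plane(v, def, axis = "x", index = 2,
                               slab_thickness = 21, cfg = cfg),
               "leaves the volume")
})

test_that("field filtering replaces invalid and non-physical values", {
  grid <- expand.grid(gi = 1:5, gj = 1:5)
  nodes <- cbind(10, grid$gi * 4, grid$gj * 4)
  u <- matrix(rep(c(1, 1, 1), each = 25), 25, 3)
  f <- displacement_field(nodes, u, rep(0.99, 25), rep("converged", 25),
                          cbind(grid$gi, grid$gj, 1L))
  # clean converged field is untouched
  expect_identical(filter_field(f), f)
  # one unconverged node amid constant field gets the neighbor median
  f2 <- f
  f2$status[13] <- "unconverged"
  f2$uz[13] <- NA
  g2 <- filter_field(f2)
  expect_equal(g2$status[13], "filtered-replaced")
  expect_equal(c(g2$uz[13], g2$uy[13], g2$ux[13]), c(1, 1, 1))
  # a 10-voxel spike amid a smooth field is replaced
  set.seed(5)
  f3 <- f
  sm <- matrix(stats::rnorm(75, sd = 0.01), 25, 3)
  f3$uz <- 1 + sm[, 1]
  f3$uy <- 1 + sm[, 2]
  f3$ux <- 1 + sm[, 3]
  f3$uz[7] <- 10
  g3 <- filter_field(f3)
  expect_equal(g3$status[7], "filtered-replaced")
  expect_lt(abs(g3$uz[7] - 1), 0.1)
  # idempotence on its own output
  expect_identical(filter_field(g3), g3)
  f4 <- f
  f4$status[] <- "unconverged"
  expect_error(filter_field(f4), "all nodes")
})

test_that("MBE and RMSE follow their definitions", {
  expect_equal(mbe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mbe(c(2, 2), c(1, 3)), 0)
  expect_equal(rmse(c(2, 2), c(1, 3)), 1)
  expect_equal(rmse(1:4, 1:4), 0)
  # the printed window-6 calibration row: P = 28.2842, O = 24.38
  expect_equal(round(mbe(28.2842, 24.38), 1), 3.9)
  expect_error(mbe(1:3, 1:2), "equal")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  # RMSE >= |MBE| on random data
  set.seed(2)
  for (i in 1:25) {
    p <- rnorm(sample(1:40, 1))
    o <- rnorm(length(p))
    expect_gte(rmse(p, o) + 1e-12, abs(mbe(p, o)))
  }
})

test_that("window calibration: zero motion and error monotonicity", {
  ph <- make_bone_phantom(phantom_spec(shape = c(64, 64, 64),
                                      canal_count = 2, canal_radius = 6,
                                      seed = 3))
  cfg <- correlation_config(prefilter_kernel = 3, search_radius = 6)
  z0 <- calibrate_window(ph, window_sizes = c(6, 8), n_steps = 2,
                         step_shift = c(0, 0, 0),
                         region = list(z = 30:33, y = 30:33, x = 32),
                         cfg = cfg)
  expect_equal(z0$mean_uYZ, c(0, 0), tolerance = 1e-9)
  expect_equal(z0$sigma_YZ, c(0, 0), tolerance = 1e-9)
  expect_equal(z0$mbe, c(0, 0), tolerance = 1e-9)
  expect_equal(z0$rmse, c(0, 0), tolerance = 1e-9)
  # noise-free sweep 6 -> 18: recovery error non-increasing, RMSE >= |MBE|
  tab <- calibrate_window(ph, window_sizes = seq(6, 18, by = 2),
                          n_steps = 3, step_shift = c(2, 2, 0),
                          region = list(z = 28:35, y = 28:35, x = 32),
                          cfg = cfg)
  expect_true(all(diff(tab$rmse) <= 1e-9))
  expect_true(all(tab$rmse + 1e-12 >= abs(tab$mbe)))
  expect_true(all(tab$sigma_YZ >= 0))
  # ideal displacement magnitude at the final step (small windows carry a
  # real recovery error, mirroring the printed calibration table)
  expect_equal(tab$mean_uYZ, rep(sqrt(6^2 + 6^2), nrow(tab)),
               tolerance = 0.01)
})
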