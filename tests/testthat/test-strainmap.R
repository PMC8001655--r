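test_that("nodal displacements are the coordinate difference", {
  r <- matrix(runif(30), 10, 3)
  expect_equal(nodal_displacements(r, r), matrix(0, 10, 3))
  d <- sweep(r, 2, c(1, 2, 3), `+`)
  expect_equal(nodal_displacements(r, d),
               matrix(rep(c(1, 2, 3), each = 10), 10, 3))
  expect_equal(nodal_displacements(d, r), -nodal_displacements(r, d))
  expect_error(nodal_displacements(r, r[1:5, ]), "match")
})

corners8 <- function() {
  as.matrix(expand.grid(z = c(0, 1), y = c(0, 1), x = c(0, 1))) * 4 + 10
}

test_that("cell affine recovers prescribed transforms exactly", {
  p <- corners8()
  ident <- voxel_affine(p, matrix(0, 8, 3))
  expect_equal(ident$linear, diag(3), tolerance = 1e-9)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-9)
  # rigid translation
  tt <- voxel_affine(p, matrix(rep(c(2, -1, 3), each = 8), 8, 3))
  expect_equal(tt$linear, diag(3), tolerance = 1e-9)
  expect_equal(tt$translation, c(2, -1, 3), tolerance = 1e-9)
  # a prescribed affine is recovered to 1e-9
  set.seed(13)
  a <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
  b <- c(0.5, -0.2, 1)
  u <- t(a %*% t(p)) + matrix(b, 8, 3, byrow = TRUE) - p
  fit <- voxel_affine(p, u)
  expect_equal(fit$linear, a, tolerance = 1e-9)
  expect_equal(fit$translation, b, tolerance = 1e-9)
  flatp <- p
  flatp[, 1] <- 10
  expect_error(voxel_affine(flatp, matrix(0, 8, 3)), "degenerate")
})

test_that("Green-Lagrange closed forms and objectivity", {
  expect_equal(green_lagrange(diag(3)), matrix(0, 3, 3))
  e <- green_lagrange(diag(c(1.1, 1, 1)))
  expect_equal(e[1, 1], (1.1^2 - 1) / 2, tolerance = 1e-15)
  expect_equal(e[-1, ], matrix(0, 2, 3), tolerance = 1e-15)
  expect_equal(max(abs(green_lagrange(rotation_z(30)))), 0,
               tolerance = 1e-12)
  # objectivity: E(R F) = E(F) for random rotations and gradients
  set.seed(41)
  for (i in 1:20) {
    f <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
    r <- random_rotation()
    expect_equal(green_lagrange(r %*% f), green_lagrange(f),
                 tolerance = 1e-12)
    expect_equal(green_lagrange(f), t(green_lagrange(f)))
  }
})

test_that("strain fields of analytic displacement fields", {
  zs <- seq(4, 24, by = 4)
  ys <- seq(4, 24, by = 4)
  xs <- seq(4, 24, by = 4)
  # uniform translation: zero strain everywhere
  f <- analytic_field(zs, ys, xs, function(z, y, x) c(2, -1, 0.5))
  sf <- strain_field(f)
  expect_equal(max(abs(as.matrix(sf[, c("E11", "E22", "E33", "E12",
                                        "E13", "E23")]))), 0,
               tolerance = 1e-9)
  expect_equal(nrow(sf), 5^3)
  # uniaxial stretch lambda = 1.02 along z
  lam <- 1.02
  f2 <- analytic_field(zs, ys, xs,
                       function(z, y, x) c((lam - 1) * z, 0, 0))
  sf2 <- strain_field(f2)
  expect_equal(sf2$E11, rep((lam^2 - 1) / 2, nrow(sf2)), tolerance = 1e-9)
  expect_equal(max(abs(sf2$E22)), 0, tolerance = 1e-12)
  # simple shear gamma = 0.05 (u_y = gamma * z): closed-form E
  g <- 0.05
  f3 <- analytic_field(zs, ys, xs, function(z, y, x) c(0, g * z, 0))
  sf3 <- strain_field(f3)
  expect_equal(sf3$E12, rep(g / 2, nrow(sf3)), tolerance = 1e-9)
  expect_equal(sf3$E11, rep(g^2 / 2, nrow(sf3)), tolerance = 1e-9)
  expect_equal(max(abs(sf3$E22)), 0, tolerance = 1e-12)
  # globally affine field: spatially constant E equal to the closed form
  set.seed(17)
  a <- diag(3) + matrix(rnorm(9, sd = 0.03), 3, 3)
  f4 <- analytic_field(zs, ys, xs, function(z, y, x) {
    as.numeric((a - diag(3)) %*% c(z, y, x))
  })
  sf4 <- strain_field(f4)
  e_ref <- green_lagrange(a)
  for (cc in list(c("E11", 1, 1), c("E22", 2, 2), c("E33", 3, 3),
                  c("E12", 1, 2), c("E13", 1, 3), c("E23", 2, 3))) {
    expect_equal(sf4[[cc[1]]],
                 rep(e_ref[as.integer(cc[2]), as.integer(cc[3])],
                     nrow(sf4)),
                 tolerance = 1e-9)
  }
  # unfiltered fields are rejected
  f5 <- f
  f5$status[3] <- "unconverged"
  expect_error(strain_field(f5), "unconverged")
})

test_that("planar fields give the in-plane strain", {
  ys <- seq(4, 24, by = 4)
  xs <- seq(4, 24, by = 4)
  g <- expand.grid(gi = seq_along(ys), gj = seq_along(xs))
  nodes <- cbind(10, ys[g$gi], xs[g$gj])
  lam <- 1.03
  u <- cbind(0, (lam - 1) * nodes[, 2], 0)
  f <- displacement_field(nodes, u, rep(1, nrow(nodes)),
                          rep("converged", nrow(nodes)),
                          as.matrix(cbind(g, 1L)))
  sf <- strain_field(f)
  expect_equal(sf$E22, rep((lam^2 - 1) / 2, nrow(sf)), tolerance = 1e-9)
  expect_equal(max(abs(sf$E33)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sf$E11)), 0, tolerance = 1e-12)
})

test_that("DVC pipeline displacement field yields the prescribed strain", {
  # prescribed uniaxial stretch on a textured phantom, tracked by DVC on a
  # 3D node lattice, then strain-mapped: E_zz matches the closed form
  v <- textured_volume(c(44, 44, 44), seed = 51)
  lam <- 1.02
  a <- diag(c(lam, 1, 1))
  ctr <- 21.5
  tr <- affine_transform(a, as.numeric((diag(3) - a) %*% rep(ctr, 3)))
  def <- apply_deformation(v, tr)
  cfg <- correlation_config(window_size = 10, prefilter_kernel = 1,
                            search_radius = 3)
  zs <- seq(14, 30, by = 8)
  grid <- expand.grid(gi = seq_along(zs), gj = seq_along(zs),
                      gk = seq_along(zs))
  nodes <- cbind(zs[grid$gi], zs[grid$gj], zs[grid$gk])
  res <- dvctomo:::cpp_track_nodes(v$data, def$data, nodes - 1,
                                   matrix(0, nrow(nodes), 3),
                                   cfg$window_size, cfg$search_radius,
                                   cfg$tolerance, cfg$max_iterations)
  expect_true(all(res$converged))
  f <- displacement_field(nodes, res$u, res$ncc,
                          rep("converged", nrow(nodes)),
                          as.matrix(grid))
  sf <- strain_field(f)
  expect_equal(sf$E11, rep((lam^2 - 1) / 2, nrow(sf)), tolerance = 0.05)
  expect_lt(max(abs(sf$E22)), 0.002)
})
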