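test_that("voxel grid validates inputs and uses the voxel-centre convention", {
  expect_error(voxel_grid(0, dims = c(4, 4, 4)), "spacing")
  expect_error(voxel_grid(1, dims = c(0, 4, 4)), "dims")
  g <- voxel_grid(2, origin = c(-4, 0, 0), dims = c(4, 2, 2))
  ax <- grid_axes(g)
  expect_equal(ax$lr, c(-3, -1, 1, 3))
  expect_equal(voxel_volume_mm3(g), 8)
})

test_that("sphere phantom volume converges to the analytic value", {
  s1 <- make_sphere_phantom(radius = 15, spacing = 1)
  v_true <- 4 / 3 * pi * 15^3
  err1 <- abs(volume_cm3(s1) * 1000 - v_true) / v_true
  expect_lt(err1, 0.02)

  s05 <- make_sphere_phantom(radius = 15, spacing = 0.5)
  err05 <- abs(volume_cm3(s05) * 1000 - v_true) / v_true
  expect_lt(err05, err1)
})

test_that("a tiny sphere at a voxel centre sets exactly one voxel", {
  g <- voxel_grid(1, origin = c(0, 0, 0), dims = c(5, 5, 5))
  s <- make_sphere_phantom(g, center = c(2.5, 2.5, 2.5), radius = 0.4)
  expect_equal(sum(s$mask), 1)
})

test_that("sphere entirely outside the grid errors", {
  g <- voxel_grid(1, dims = c(5, 5, 5))
  expect_error(
    make_sphere_phantom(g, center = c(100, 100, 100), radius = 2),
    "empty"
  )
})

test_that("ellipsoid phantom matches the analytic volume and degenerates to a sphere", {
  semi <- c(20, 12, 9)
  e <- make_ellipsoid_phantom(semi_axes = semi, spacing = 1)
  v_true <- 4 / 3 * pi * prod(semi)
  expect_lt(abs(volume_cm3(e) * 1000 - v_true) / v_true, 0.02)

  g <- voxel_grid(1, dims = c(31, 31, 31))
  sph <- make_sphere_phantom(g, center = c(15.5, 15.5, 15.5), radius = 10)
  ell <- make_ellipsoid_phantom(g, center = c(15.5, 15.5, 15.5),
                                semi_axes = c(10, 10, 10))
  expect_identical(sph$mask, ell$mask)
  expect_error(make_ellipsoid_phantom(semi_axes = c(5, 0, 5)), "semi_axes")
})

test_that("margin expansion is the Euclidean-distance dilation", {
  s <- make_sphere_phantom(radius = 6, spacing = 1)
  expect_error(expand_margin(s, -1), "non-negative")
  expect_identical(expand_margin(s, 0)$mask, s$mask)

  # exact agreement with the brute-force distance-transform oracle,
  # computed on the same enlarged grid
  d <- expand_margin(s, 3)
  oracle <- brute_dilate(
    embed_mask_for_test(s, d$grid), d$grid$spacing, 3
  )
  expect_identical(d$mask, oracle)
})

test_that("dilating a ball gives a larger ball and the GTV->CTV->PTV chain", {
  gtv <- make_sphere_phantom(radius = 10, spacing = 1, label = "GTV")
  ctv <- expand_margin(gtv, 2)
  ptv <- expand_margin(ctv, 4)
  expect_equal(ctv$label, "CTV")
  expect_equal(ptv$label, "PTV")
  # radius within one voxel spacing of the analytic dilation
  r_ctv <- (volume_cm3(ctv) * 1000 * 3 / (4 * pi))^(1 / 3)
  r_ptv <- (volume_cm3(ptv) * 1000 * 3 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_ctv - 12), 1)
  expect_lt(abs(r_ptv - 16), 1)
})

test_that("dilation is monotone in margin and composes within one voxel", {
  s <- make_sphere_phantom(radius = 8, spacing = 1)
  v <- vapply(c(0, 1, 2, 4), function(m) volume_cm3(expand_margin(s, m)),
              numeric(1))
  expect_true(all(diff(v) > 0))

  ab <- expand_margin(expand_margin(s, 2), 3)
  once <- expand_margin(s, 5)
  r_ab <- (volume_cm3(ab) * 1000 * 3 / (4 * pi))^(1 / 3)
  r_once <- (volume_cm3(once) * 1000 * 3 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_ab - r_once), 1)
  # composed dilation always contains the set dilated by each part alone
  expect_true(all(embed_mask_for_test(expand_margin(s, 2), ab$grid) <= ab$mask))
})

test_that("axis lengths match analytic shapes within one voxel spacing", {
  sph <- make_sphere_phantom(radius = 15, spacing = 1)
  ax <- axis_lengths(sph)
  expect_lte(abs(ax$a_max - 30), 1)
  expect_lte(abs(ax$a_min - 30), 1)

  ell <- make_ellipsoid_phantom(semi_axes = c(28.40, 18.18, 18.18),
                                spacing = 1)
  ax <- axis_lengths(ell)
  expect_lt(abs(ax$a_max - 56.80), 1)
  expect_lt(abs(ax$a_min - 36.36), 1)
  expect_gte(ax$a_max, ax$a_min)
})

test_that("long axis agrees with the brute-force Feret oracle", {
  withr::with_seed(42, {
    semi <- c(14, 9, 6)
    e <- make_ellipsoid_phantom(semi_axes = semi, spacing = 2)
    P <- irisopt:::surface_coords(e)
    ax <- axis_lengths(e)
    expect_equal(ax$a_max, brute_feret(P) + 2, tolerance = 1e-12)
  })
})

test_that("axis lengths are invariant under rigid translation of the mask", {
  e1 <- make_ellipsoid_phantom(center = c(0, 0, 0),
                               semi_axes = c(16, 10, 8), spacing = 2)
  e2 <- make_ellipsoid_phantom(center = c(7, -13, 29),
                               semi_axes = c(16, 10, 8), spacing = 2)
  a1 <- axis_lengths(e1)
  a2 <- axis_lengths(e2)
  expect_lt(abs(a1$a_max - a2$a_max), 2)
  expect_lt(abs(a1$a_min - a2$a_min), 2)
})

test_that("degenerate single-voxel structures report the voxel spacing", {
  g <- voxel_grid(2, dims = c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  ax <- axis_lengths(structure_mask(g, m))
  expect_equal(ax$a_max, 2)
  expect_equal(ax$a_min, 2)
  m[] <- FALSE
  expect_error(axis_lengths(structure_mask(g, m)), "empty")
})

test_that("halving the spacing changes volume and axes by less than a coarse voxel", {
  e1 <- make_ellipsoid_phantom(semi_axes = c(15, 10, 8), spacing = 2)
  e2 <- make_ellipsoid_phantom(semi_axes = c(15, 10, 8), spacing = 1)
  expect_lt(
    abs(volume_cm3(e1) - volume_cm3(e2)) / volume_cm3(e2), 0.05
  )
  a1 <- axis_lengths(e1)
  a2 <- axis_lengths(e2)
  expect_lt(abs(a1$a_max - a2$a_max), 2)
  expect_lt(abs(a1$a_min - a2$a_min), 2)
})

test_that("masks round-trip through NIfTI preserving grid and voxels", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  s <- make_ellipsoid_phantom(semi_axes = c(12, 8, 6), spacing = 2,
                              label = "PTV")
  write_mask(s, path)
  r <- read_mask(path, label = "PTV")
  expect_identical(r$mask, s$mask)
  expect_equal(r$grid$spacing, s$grid$spacing)
  expect_equal(r$grid$origin, s$grid$origin, tolerance = 1e-5)
})
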