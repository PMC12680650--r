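test_that("volume is voxel count times voxel volume", {
  m <- region_mask(array(TRUE, c(10, 10, 10)), "r", c(0.1, 0.1, 0.2))
  expect_equal(mask_volume(m), 1000 * 0.002)
  empty <- region_mask(array(FALSE, c(4, 4, 4)), "r", c(0.1, 0.1, 0.2))
  expect_equal(mask_volume(empty), 0)
})

test_that("digitised sphere recovers analytic volume, area and sphericity", {
  m <- ball_mask(2, 0.05, 88)
  v_true <- 4 / 3 * pi * 8
  a_true <- 4 * pi * 4
  v <- mask_volume(m)
  a <- surface_area(m)
  expect_lt(abs(v / v_true - 1), 0.02)
  expect_lt(abs(a / a_true - 1), 0.03)
  expect_lt(abs(sphericity(v, a) - 1), 0.02)
})

test_that("prolate 2:1:1 spheroid matches its closed-form sphericity", {
  m <- ellipsoid_mask(c(2, 1, 1), 0.05, 88)
  v_true <- 4 / 3 * pi * 2
  a_true <- prolate_area(2, 1)
  sph_true <- pi^(1 / 3) * (6 * v_true)^(2 / 3) / a_true
  expect_equal(sph_true, 0.929, tolerance = 5e-4)
  sph <- sphericity(mask_volume(m), surface_area(m))
  expect_lt(abs(sph / sph_true - 1), 0.02)
})

test_that("cube sphericity matches the closed form", {
  # a large digitised cube is exact: its mask is the cube
  n <- 40
  mask <- array(FALSE, c(n + 8, n + 8, n + 8))
  mask[5:(n + 4), 5:(n + 4), 5:(n + 4)] <- TRUE
  m <- region_mask(mask, "cube", c(0.1, 0.1, 0.1))
  s <- n * 0.1
  expect_equal(mask_volume(m), s^3)
  sph_true <- pi^(1 / 3) * 6^(2 / 3) / 6
  expect_equal(sph_true, 0.806, tolerance = 5e-4)
  # mesh smoothing rounds the corners; a cube's area estimate is within ~5%
  sph <- sphericity(mask_volume(m), surface_area(m))
  expect_lt(abs(sph - sph_true), 0.05)
  expect_error(sphericity(0, 1), "positive")
})

test_that("single-voxel surface is positive and bounded by its faces", {
  mask <- array(FALSE, c(7, 7, 7))
  mask[4, 4, 4] <- TRUE
  m <- region_mask(mask, "dot", c(0.1, 0.1, 0.1))
  a <- surface_area(m)
  expect_gt(a, 0)
  expect_lte(a, 0.06)
  empty <- region_mask(array(FALSE, c(4, 4, 4)), "r", c(0.1, 0.1, 0.1))
  expect_error(surface_area(empty), "empty mask")
})

test_that("surface area scales as pitch squared", {
  m1 <- ball_mask(0.8, 0.05, 44)
  m2 <- region_mask(m1$mask, m1$region, m1$voxel_size * 2)
  expect_equal(surface_area(m2), 4 * surface_area(m1))
})

test_that("projection area matches the analytic disc and is axis-symmetric", {
  m <- ball_mask(2, 0.05, 88)
  expect_lt(abs(projection_area(m, "z") / (pi * 4) - 1), 0.02)
  # single voxel projects to one pixel
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(projection_area(region_mask(one, "r", c(0.1, 0.1, 0.2)), "z"),
               0.01)
  # phantom with a circular-section head: y and z projections agree
  # (the default head is a paddle, wider in y than z, so force b = c)
  spec <- phantom_spec(nucleus_semiaxes = c(1.1, 0.6, 0.6), noise_sd = 0)
  masks <- segment_cell(render_tomogram(spec, voxel_size = c(0.1, 0.1, 0.1),
                                        grid_shape = c(72, 72, 72)))
  px <- projection_area(masks$whole, "y")
  py <- projection_area(masks$whole, "z")
  expect_lt(abs(px / py - 1), 0.01)
})

test_that("dry mass matches the closed form and behaves linearly", {
  m <- ball_mask(2, 0.05, 88)
  g <- array(1.337, dim(m$mask))
  g[m$mask] <- 1.387
  tom <- ri_tomogram(g, m$voxel_size, 1.337)
  dm <- dry_mass(tom, m)
  v <- mask_volume(m)
  expect_equal(as.numeric(dm), (0.05 / 0.185) * v, tolerance = 1e-10)
  expect_equal(as.numeric(dm), 9.057, tolerance = 0.02)
  # doubling the RI excess doubles the mass
  g2 <- array(1.337, dim(m$mask)); g2[m$mask] <- 1.437
  tom2 <- ri_tomogram(g2, m$voxel_size, 1.337)
  expect_equal(as.numeric(dry_mass(tom2, m)), 2 * as.numeric(dm))
  # RI equal to the medium: zero mass
  tom0 <- ri_tomogram(array(1.337, dim(m$mask)), m$voxel_size, 1.337)
  expect_equal(as.numeric(dry_mass(tom0, m)), 0)
  expect_error(dry_mass(tom, m, alpha = 0), "alpha")
})

test_that("sub-medium voxels are clipped and counted, not subtracted", {
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
  m <- region_mask(mask, "r", c(0.1, 0.1, 0.1))
  g <- array(1.337, c(4, 4, 4))
  g[1, 1, 1] <- 1.437   # + 0.1
  g[2, 1, 1] <- 1.237   # - 0.1, clipped
  tom <- ri_tomogram(g, m$voxel_size, 1.337)
  dm <- dry_mass(tom, m)
  expect_equal(as.numeric(dm), 0.1 / 0.185 * 0.001)
  expect_equal(attr(dm, "n_clipped_negative"), 1)
})

test_that("dry mass is additive over disjoint masks", {
  tom <- render_tomogram(phantom_spec(seed = 3))
  masks <- segment_cell(tom)
  union <- region_mask(masks$midpiece$mask | masks$nucleus$mask, "u",
                       masks$whole$voxel_size)
  expect_equal(as.numeric(dry_mass(tom, union)),
               as.numeric(dry_mass(tom, masks$midpiece)) +
                 as.numeric(dry_mass(tom, masks$nucleus)))
})

test_that("concentration divides mass by volume and rejects empty regions", {
  expect_equal(ri_concentration(9.057, 33.510), 0.2703, tolerance = 1e-4)
  expect_error(ri_concentration(1, 0), "zero volume")
  # homogeneous region: concentration independent of size
  for (r in c(0.5, 1)) {
    m <- ball_mask(r, 0.05, 48)
    g <- array(1.337, dim(m$mask)); g[m$mask] <- 1.387
    tom <- ri_tomogram(g, m$voxel_size, 1.337)
    expect_equal(ri_concentration(dry_mass(tom, m), mask_volume(m)),
                 0.05 / 0.185, tolerance = 1e-10)
  }
})

test_that("sphericity never exceeds 1 beyond discretisation slack on random
           ellipsoids", {
  withr::with_seed(2024, {
    for (i in 1:40) {
      semi <- runif(3, 0.4, 1.2)
      m <- ellipsoid_mask(semi, 0.05, 56)
      s <- sphericity(mask_volume(m), surface_area(m))
      expect_lte(s, 1.02)
      expect_gt(s, 0.5)
    }
  })
})

test_that("mesh-enclosed volume agrees with the voxel count for smooth
           shapes", {
  for (r in c(0.8, 1.5)) {
    m <- ball_mask(r, 0.05, 72)
    ms <- spermHT:::mask_mesh_stats(m)
    expect_lt(abs(ms[["volume"]] / mask_volume(m) - 1), 0.05)
  }
})

test_that("halving the pitch moves sphere estimates closer to the analytic
           values", {
  v_true <- 4 / 3 * pi
  a_true <- 4 * pi
  coarse <- ball_mask(1, 0.1, 26)
  fine <- ball_mask(1, 0.05, 52)
  expect_lt(abs(mask_volume(fine) - v_true), abs(mask_volume(coarse) - v_true))
  expect_lt(abs(surface_area(fine) - a_true),
            abs(surface_area(coarse) - a_true))
})

test_that("cell_morphometry returns the full descriptor set per region", {
  tom <- render_tomogram(phantom_spec(seed = 8))
  tab <- cell_morphometry(tom, segment_cell(tom))
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$region, c("whole", "midpiece", "nucleus"))
  expect_true(all(tab$volume > 0))
  expect_true(all(tab$dry_mass > 0))
  expect_equal(tab$concentration * tab$volume, tab$dry_mass)
  expect_equal(tab$volume,
               tab$voxel_count * prod(tom$voxel_size))
  expect_true(all(tab$sphericity < 1.02))
})
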