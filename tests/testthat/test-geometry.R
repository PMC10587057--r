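test_that("gyroid field matches its closed form and odd symmetry", {
  expect_identical(gyroid_value(0, 0, 0), 0)
  expect_equal(gyroid_value(0.25, 0, 0), 1)
  set.seed(1)
  x <- runif(100, -2, 2)
  y <- runif(100, -2, 2)
  z <- runif(100, -2, 2)
  expect_equal(gyroid_value(-x, -y, -z), -gyroid_value(x, y, z))
  expect_true(all(abs(gyroid_value(x, y, z)) <= 1.5))
})

test_that("solid fraction is a half at c = 0 and monotone in c", {
  expect_equal(solid_fraction(0, 40), 0.5, tolerance = 1 / 40)
  expect_equal(solid_fraction(1.5, 40), 0)
  cs <- seq(-1.5, 1.5, length.out = 50)
  fr <- solid_fraction(cs, 40)
  expect_true(all(diff(fr) <= 0))
  expect_true(solid_fraction(-0.5, 40) >= solid_fraction(0, 40))
  expect_true(solid_fraction(0, 40) >= solid_fraction(0.5, 40))
})

test_that("isovalue calibration inverts the solid fraction on the ladder", {
  expect_equal(calibrate_isovalue(0.5), 0, tolerance = 0.01)
  expect_lt(calibrate_isovalue(0.2), 0)
  expect_gt(calibrate_isovalue(0.9), 0)
  p <- porosity_ladder()
  recovered <- 1 - solid_fraction(calibrate_isovalue(p, 40), 40)
  expect_lte(max(abs(recovered - p)), 0.01)
  expect_error(calibrate_isovalue(0.1), "0.2")
})

test_that("porosity matrix validation enforces shape, range and ladder", {
  expect_s3_class(porosity_matrix(array(0.5, c(3, 3, 3))), "porosity_matrix")
  expect_error(porosity_matrix(array(0.5, c(5, 5, 5))), "edge")
  expect_error(porosity_matrix(array(0.1, c(3, 3, 3))), "0.2")
  expect_error(porosity_matrix(array(0.95, c(2, 2, 2))), "0.2")
  expect_error(porosity_matrix(array(0.55, c(2, 2, 2)), discrete = TRUE),
               "multiple")
})

test_that("isovalue field is calibrated at subunit centers and linear between", {
  # odd voxels/unit puts a voxel center exactly on each subunit center
  geo <- unit_cell_spec(voxels_per_unit = 9)
  m <- porosity_matrix(array(0.5, c(3, 3, 3)))
  f <- build_isovalue_field(m, geo)
  expect_equal(max(abs(f)), 0, tolerance = 0.01)
  mg <- array(rep(c(0.3, 0.5, 0.7), each = 9), c(3, 3, 3))  # graded along z
  f <- build_isovalue_field(aperm(mg, c(3, 2, 1)), geo)     # graded along x
  cvals <- calibrate_isovalue(c(0.3, 0.5, 0.7))
  centers <- c(5, 14, 23)  # voxel indices on the subunit centers
  for (k in 1:3)
    expect_equal(f[centers[k], 1, 1], cvals[k], tolerance = 1e-12)
  # between neighbouring centers the profile is linear: midpoint = average
  between <- (f[9, 1, 1] + f[10, 1, 1]) / 2
  expect_equal(between, mean(cvals[1:2]), tolerance = 1e-12)
})

test_that("voxelization yields the right shape and recovers porosities", {
  m <- porosity_matrix(array(0.5, c(3, 3, 3)))
  g <- voxelize(m)
  expect_equal(dim(g), c(60, 60, 60))
  expect_true(all(g %in% c(0L, 1L)))
  expect_equal(measure_porosity(g), 0.5, tolerance = 0.02)
  for (s in c(2, 4)) {
    geo <- unit_cell_spec(cells_per_axis = s, voxels_per_unit = 8)
    gs <- voxelize(porosity_matrix(array(0.4, rep(s, 3))), geo)
    expect_equal(dim(gs), rep(8 * s, 3))
  }
  # a layered grading (one ladder step between neighbours): the interior
  # subunit's measured porosity tracks its nominal value
  mg <- porosity_matrix(array(rep(c(0.4, 0.5, 0.6), each = 9), c(3, 3, 3)))
  gg <- voxelize(mg)
  sp <- subunit_porosity(gg)
  expect_lt(abs(sp[2, 2, 2] - mg[2, 2, 2]), 0.03)
  expect_lt(abs(measure_porosity(gg) - mean(mg)), 0.03)
  # scaffold-level porosity stays accurate even for strongly mixed designs
  set.seed(4)
  mr <- generate_matrix("random", 3)
  expect_lt(abs(measure_porosity(voxelize(mr)) - mean(mr)), 0.03)
})

test_that("porosity and mass fraction are complementary", {
  g <- array(1L, c(4, 4, 4))
  expect_equal(measure_porosity(g), 0)
  expect_equal(mass_fraction(array(0L, c(4, 4, 4))), 0)
  chk <- array(as.integer((slice.index(array(0, c(2, 2, 2)), 1) +
                           slice.index(array(0, c(2, 2, 2)), 2) +
                           slice.index(array(0, c(2, 2, 2)), 3)) %% 2),
               c(2, 2, 2))
  expect_equal(measure_porosity(chk), 0.5)
  expect_equal(measure_porosity(chk) + mass_fraction(chk), 1)
  expect_error(measure_porosity(array(0.5, c(2, 2, 2))), "binary")
})

test_that("expansion replicates blocks and contraction inverts it", {
  m <- porosity_matrix(array(0.4, c(3, 3, 3)))
  ex <- expand_matrix(m)
  expect_equal(dim(ex), c(12, 12, 12))
  expect_true(all(ex == 0.4))
  m2 <- generate_matrix("random", 3)
  ex2 <- expand_matrix(m2)
  expect_true(all(ex2[1:4, 1:4, 1:4] == m2[1, 1, 1]))
  set.seed(8)
  for (s in c(2, 3, 4)) {
    for (i in 1:15) {
      m <- generate_matrix("random", s)
      expect_equal(contract_matrix(expand_matrix(m), s), unclass(m),
                   ignore_attr = TRUE)
    }
  }
  expect_error(expand_matrix(array(0.5, c(5, 5, 5))), "edge")
})

test_that("surface export writes a well-formed STL spanning the scaffold", {
  path <- tempfile(fileext = ".stl")
  on.exit(unlink(path))
  geo <- unit_cell_spec(voxels_per_unit = 10)
  ntri <- export_surface(porosity_matrix(array(0.5, c(3, 3, 3))), geo, path)
  expect_gt(ntri, 1000)
  v <- read_stl(path)
  expect_equal(nrow(v), 3 * ntri)
  bbox <- apply(v, 2, range)
  expect_equal(as.vector(bbox[2, ] - bbox[1, ]), rep(6, 3), tolerance = 0.1)
  expect_error(export_surface(porosity_matrix(array(0.15, c(3, 3, 3))), geo,
                              path))
})
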