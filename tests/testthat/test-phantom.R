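test_that("cylinder truth has equal diameters everywhere and no misalignment", {
  tr <- analytic_truth(cylinder_spec(200))
  expect_equal(tr$ba_min, 400)
  expect_equal(tr$ba_max, 400)
  expect_equal(tr$ma_min, 400)
  expect_equal(tr$ma_max, 400)
  expect_equal(tr$centre_misalignment, 0)
  expect_equal(tr$hole_height, 300)
  # closed forms: V = pi r^2 h, SA = 2 pi r (h + r) within quadrature error
  expect_equal(tr$volume, pi * 200^2 * 300, tolerance = 1e-3)
  expect_equal(tr$surface_area, 2 * pi * 200 * (300 + 200), tolerance = 5e-3)
})

test_that("hourglass truth: MA at the waist, BA at the base", {
  spec <- phantom_spec(nx = 200L, ny = 96L, nz = 49L,
                       spacing = voxel_spacing(10, 5, 25),
                       ilm_um = 100, rpe_um = 400,
                       base = c(400, 400, 0), waist = c(175, 175, 0),
                       top = c(300, 300, 0), waist_frac = 0.5,
                       tilt_um = c(0, 0))
  tr <- analytic_truth(spec)
  expect_equal(tr$ma_min, 350)
  expect_equal(tr$ma_max, 350)
  expect_equal(tr$ma_height, 0.5 * 300, tolerance = 1e-6)
  expect_equal(tr$ba_min, 800)
  expect_equal(tr$ba_max, 800)
})

test_that("rotated-ellipse truth: Feret equals the axes at the stated meridian", {
  spec <- phantom_spec(nx = 220L, ny = 96L, nz = 49L,
                       spacing = voxel_spacing(10, 5, 25),
                       ilm_um = 100, rpe_um = 400,
                       base = c(400, 300, 30), waist = c(200, 150, 30),
                       top = c(250, 190, 30), waist_frac = 0.5,
                       tilt_um = c(0, 0))
  tr <- analytic_truth(spec)
  expect_equal(tr$ba_max, 800)
  expect_equal(tr$ba_min, 600)
  expect_equal(tr$ba_angle_max, 30)
  expect_equal(tr$ba_angle_min, 120)
})

test_that("a cone tapering upward puts the minimum area at the 90% bound", {
  spec <- cylinder_spec(200)
  spec$top <- c(1, 1, 0); spec$waist <- c(100.5, 100.5, 0)
  # linear taper 200 -> 1; area decreases with height
  tr <- analytic_truth(spec)
  expect_equal(tr$ma_height, 0.9 * 300, tolerance = 1e-2)
})

test_that("phantom truth is invariant under rigid meridian rotation", {
  s1 <- test_spec()
  s2 <- test_spec(base = c(250, 210, 65), waist = c(150, 120, 55),
                  top = c(180, 150, 75))
  t1 <- analytic_truth(s1); t2 <- analytic_truth(s2)
  for (f in c("ba_min", "ba_max", "ma_min", "ma_max", "volume",
              "hole_height", "centre_misalignment"))
    expect_equal(t1[[f]], t2[[f]], tolerance = 1e-9, label = f)
  # the lateral-surface quadrature mesh rotates with the meridians
  expect_equal(t1$surface_area, t2$surface_area, tolerance = 1e-3)
  expect_equal(angdiff(t2$ba_angle_max, t1$ba_angle_max), 45, tolerance = 1e-9)
})

test_that("truth volume quadrature is converged at the default step", {
  spec <- test_spec()
  v1 <- analytic_truth(spec, step_um = 1)$volume
  v05 <- analytic_truth(spec, step_um = 0.5)$volume
  expect_lt(abs(v1 - v05) / v05, 1e-3)
})

test_that("rasterised truth mask volume approaches the analytic value", {
  # near-isotropic 5 um grid: voxel-count volume within 2%
  spec <- phantom_spec(nx = 140L, ny = 80L, nz = 140L,
                       spacing = voxel_spacing(5, 5, 5),
                       ilm_um = 50, rpe_um = 300,
                       base = c(250, 210, 20), waist = c(150, 120, 10),
                       top = c(180, 150, 30), waist_frac = 0.5,
                       tilt_um = c(30, 30))
  ph <- generate_phantom(spec)
  expect_lt(abs(hole_volume(ph$truth) / ph$truth_params$volume - 1), 0.02)
})

test_that("speckle is unit-mean, has the requested spread, and is reproducible", {
  vol <- oct_volume(array(100, c(60, 60, 30)), voxel_spacing(10, 5, 25))
  expect_identical(add_speckle_noise(vol, 0)$intensities, vol$intensities)
  n1 <- add_speckle_noise(vol, 0.2, seed = 5)
  n2 <- add_speckle_noise(vol, 0.2, seed = 5)
  expect_identical(n1$intensities, n2$intensities)
  expect_false(identical(n1$intensities,
                         add_speckle_noise(vol, 0.2, seed = 6)$intensities))
  x <- as.vector(n1$intensities)   # 1.08e5 voxels
  expect_lt(abs(mean(x) - 100) / 100, 0.01)
  expect_lt(abs(sd(x) - 20) / 20, 0.10)
  expect_error(add_speckle_noise(vol, -0.1), "non-negative")
})

test_that("phantom generation with a fixed seed is bit-identical", {
  p1 <- generate_phantom(test_spec(speckle_s = 0.15, seed = 11))
  p2 <- generate_phantom(test_spec(speckle_s = 0.15, seed = 11))
  expect_identical(p1$volume$intensities, p2$volume$intensities)
  expect_identical(p1$truth$voxels, p2$truth$voxels)
})

test_that("spec validation rejects impossible phantoms", {
  expect_error(test_spec(base = c(700, 600, 0)), "footprint")
  expect_error(test_spec(waist_frac = 1.2), "waist_frac")
  expect_error(test_spec(ilm_um = 450), "RPE depth")
  expect_error(test_spec(speckle_s = -1), "non-negative")
})

test_that("the operculum flag adds tissue above the hole without touching the truth", {
  p0 <- generate_phantom(test_spec())
  p1 <- generate_phantom(test_spec(operculum = TRUE))
  expect_identical(p0$truth$voxels, p1$truth$voxels)
  expect_gt(sum(p1$volume$intensities), sum(p0$volume$intensities))
})
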