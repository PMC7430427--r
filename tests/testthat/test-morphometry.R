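test_that("Feret diameters match closed forms on simple shapes", {
  # axis-aligned 200 x 100 um rectangle of pixels
  rect <- matrix(TRUE, 20, 10)
  f <- feret_diameters(rect, c(10, 10))
  expect_equal(f$feret_min, 100, tolerance = 1e-9)
  expect_equal(f$feret_max, sqrt(200^2 + 100^2), tolerance = 1e-9)
  expect_equal(f$angle_min %% 90, 0, tolerance = 1e-9)
  # digitised circle r = 50 um at 1 um pixels
  n <- 121
  xs <- (seq_len(n) - 1) - 60
  circ <- outer(xs, xs, function(a, b) a^2 + b^2 <= 50^2)
  f <- feret_diameters(circ, c(1, 1))
  expect_equal(f$feret_min, 100, tolerance = 0.02)
  expect_equal(f$feret_max, 100, tolerance = 0.02)
  # single pixel has the pixel's own extent
  one <- matrix(TRUE, 1, 1)
  f1 <- feret_diameters(one, c(5.47, 30))
  expect_equal(f1$feret_min, 5.47, tolerance = 1e-9)
  expect_equal(f1$feret_max, sqrt(5.47^2 + 30^2), tolerance = 1e-9)
  expect_error(feret_diameters(matrix(FALSE, 3, 3), c(1, 1)), "empty")
})

test_that("a rotated ellipse yields its axes at the right caliper angles", {
  xs <- seq(-250, 250, by = 1)
  th <- 30 * pi / 180
  grid <- expand.grid(x = xs, z = xs)
  pr <- grid$x * cos(th) + grid$z * sin(th)
  qr <- -grid$x * sin(th) + grid$z * cos(th)
  m <- matrix((pr / 200)^2 + (qr / 150)^2 <= 1, length(xs))
  f <- feret_diameters(m, c(1, 1))
  expect_equal(f$feret_max, 400, tolerance = 0.01)
  expect_equal(f$feret_min, 300, tolerance = 0.01)
  expect_lte(angdiff(f$angle_max, 30), 2)
  expect_lte(angdiff(f$angle_min, 120), 2)
})

test_that("rotating calipers agree with the brute-force rotation oracle", {
  set.seed(77)
  for (i in 1:50) {
    poly <- random_convex_polygon()
    f <- feret_diameters(poly)
    o <- feret_bruteforce(poly)
    expect_lt(abs(f$feret_max - o$feret_max) / o$feret_max, 0.005)
    expect_lt(abs(f$feret_min - o$feret_min) / max(o$feret_min, 1e-9), 0.005)
  }
})

test_that("sections of a cylinder truth mask are circular and correctly sized", {
  spec <- cylinder_spec(200)
  ph <- generate_phantom(spec)
  secs <- extract_sections(ph$truth, spec$rpe_um)
  expect_true(all(abs(secs$area_um2 / (pi * 200^2) - 1) < 0.02))
  dx <- spec$spacing[1]
  expect_true(all(abs(secs$feret_min_um - 400) <= 2 * dx + 25))
  expect_true(all(abs(secs$feret_max_um - 400) <= 2 * dx + 25))
})

test_that("a single voxel gives one section of one pixel area", {
  sp <- voxel_spacing(10, 5, 25)
  m <- array(FALSE, c(10, 10, 5)); m[4, 6, 3] <- TRUE
  secs <- extract_sections(hole_mask(m, sp), rpe = 45)
  expect_equal(nrow(secs), 1L)
  expect_equal(secs$area_um2, 10 * 25)
  expect_error(extract_sections(hole_mask(array(FALSE, c(4, 4, 4)), sp), 45),
               "empty")
})

test_that("only the largest in-plane component is measured", {
  sp <- voxel_spacing(10, 5, 25)
  m <- array(FALSE, c(30, 4, 20))
  m[2:11, 2, 2:9] <- TRUE      # 80 px blob
  m[20:23, 2, 15:17] <- TRUE   # 12 px blob
  secs <- extract_sections(hole_mask(m, sp), rpe = 10)
  expect_equal(secs$n_pixels, 80L)
})

test_that("minimum-area selection respects the 20-90% band and ties", {
  h <- 300
  secs <- data.frame(height_um = seq(10, 290, by = 10),
                     area_um2 = 1000)
  class(secs) <- c("mh_sections", "data.frame")
  ma <- find_minimum_area(secs, h)
  expect_equal(ma$height_um, 60)   # lowest section in [60, 270]
  # a distinct waist wins
  secs$area_um2[secs$height_um == 150] <- 500
  expect_equal(find_minimum_area(secs, h)$height_um, 150)
  # minimum outside the band is clipped to the band edge
  secs$area_um2 <- 3000 - 5 * secs$height_um  # strictly decreasing
  expect_equal(find_minimum_area(secs, h)$height_um, 270)
  expect_error(find_minimum_area(secs[secs$height_um < 50, , drop = FALSE], h),
               "band")
})

test_that("boundary sections of truth masks match the phantom geometry", {
  spec <- phantom_spec(nx = 200L, ny = 96L, nz = 49L,
                       spacing = voxel_spacing(10, 5, 25),
                       ilm_um = 100, rpe_um = 400,
                       base = c(400, 400, 0), waist = c(175, 175, 0),
                       top = c(300, 300, 0), waist_frac = 0.5,
                       tilt_um = c(0, 0))
  ph <- generate_phantom(spec)
  bt <- boundary_sections(ph$truth, spec$rpe_um)
  dx <- spec$spacing[1]
  expect_lte(abs(bt$base$feret_min_um - 800), 2 * dx + 25)
  expect_lte(abs(bt$base$feret_max_um - 800), 2 * dx + 25)
  expect_true(bt$full_thickness)
  # cylinder: top equals base
  cyl <- generate_phantom(cylinder_spec(200))
  bc <- boundary_sections(cyl$truth, 400)
  expect_equal(bc$top$area_um2, bc$base$area_um2, tolerance = 0.02)
})

test_that("hole and retinal heights are measured from the RPE level", {
  spec <- test_spec()
  ph <- generate_phantom(spec)
  sf <- list(rpe = surface_map(matrix(400, 120, 25), "RPE"),
             ilm = surface_map(matrix(100, 120, 25), "ILM"))
  hh <- hole_heights(ph$truth, sf$rpe, sf$ilm)
  expect_lte(abs(hh$hole_height - 300), 5)
  expect_lte(abs(hh$retinal_height - 300), 5)
  # one voxel adjacent to the base plane spans one voxel of height
  m <- array(FALSE, c(10, 10, 5)); m[5, 8, 3] <- TRUE   # y = 35, level 40
  one <- hole_mask(m, voxel_spacing(10, 5, 25))
  h1 <- hole_heights(one, 40, surface_map(matrix(15, 10, 5), "ILM"))
  expect_equal(h1$hole_height, 5)
})

test_that("surface area matches closed forms for digitised solids", {
  c0 <- 250
  sph <- digitise(function(x, y, z) (x - c0)^2 + (y - c0)^2 + (z - c0)^2 <= 200^2,
                  c(101, 101, 101))
  expect_lt(abs(surface_area(sph) / (4 * pi * 200^2) - 1), 0.05)
  cub <- digitise(function(x, y, z)
    abs(x - c0) <= 50 & abs(y - c0) <= 50 & abs(z - c0) <= 50, c(101, 101, 101))
  expect_lt(abs(surface_area(cub) / 6e4 - 1), 0.05)
  cyl <- digitise(function(x, y, z)
    (x - c0)^2 + (z - c0)^2 <= 200^2 & abs(y - c0) <= 150, c(101, 101, 101))
  expect_lt(abs(surface_area(cyl) / (2 * pi * 200 * (300 + 200)) - 1), 0.05)
})

test_that("hole volume is voxel count times voxel volume", {
  sp <- voxel_spacing(5.47, 3.87, 30)
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  expect_equal(hole_volume(hole_mask(m, sp)), 5.47 * 3.87 * 30)
  expect_equal(hole_volume(hole_mask(array(FALSE, c(4, 4, 4)), sp)), 0)
  c0 <- 250
  cyl <- digitise(function(x, y, z)
    (x - c0)^2 + (z - c0)^2 <= 200^2 & abs(y - c0) <= 150, c(101, 101, 101))
  expect_lt(abs(hole_volume(cyl) / (pi * 200^2 * 300) - 1), 0.02)
})

test_that("the centre line reports the base-to-top misalignment", {
  # sheared cylinder: top centre offset by (173.2, 0) um
  spec <- cylinder_spec(150)
  spec$tilt_um <- c(173.2, 0)
  ph <- generate_phantom(spec)
  secs <- extract_sections(ph$truth, spec$rpe_um)
  cl <- centre_line(secs)
  expect_lte(abs(cl$centre_misalignment - 173.2 * (295 / 300)), 2 * 10 + 5)
  # shear purely along Z leaves the X component near zero
  specz <- cylinder_spec(150); specz$tilt_um <- c(0, 100)
  phz <- generate_phantom(specz)
  sz <- extract_sections(phz$truth, specz$rpe_um)
  dxc <- abs(sz$cx_um[nrow(sz)] - sz$cx_um[1])
  expect_lte(dxc, 10)
  # vertical cylinder: no misalignment
  ph0 <- generate_phantom(cylinder_spec(150))
  s0 <- extract_sections(ph0$truth, 400)
  expect_lte(centre_line(s0)$centre_misalignment, 10)
})

test_that("IVTS classification uses the published edges and is monotone", {
  expect_equal(classify_ivts(240), "small")
  expect_equal(classify_ivts(400), "medium")
  expect_equal(classify_ivts(401), "large")
  expect_equal(classify_ivts(250), "small")   # documented boundary convention
  cls <- classify_ivts(seq(0, 1000, by = 1))
  ord <- c(small = 1, medium = 2, large = 3)
  expect_true(all(diff(ord[cls]) >= 0))
  expect_error(classify_ivts(-1), "non-negative")
})

test_that("truncated-cone volume matches closed forms and slab quadrature", {
  expect_equal(truncated_cone_volume(400, 400, 300), pi * 300 * 400^2 / 4,
               tolerance = 1e-12)
  expect_equal(truncated_cone_volume(0, 400, 300), pi * 300 * 400^2 / 12,
               tolerance = 1e-12)
  # frustum from cohort-scale calliper values, against slab integration
  slab_oracle <- function(mld, bd, h, n = 20000) {
    t <- (seq_len(n) - 0.5) / n
    r <- (mld + t * (bd - mld)) / 2
    sum(pi * r^2) * h / n
  }
  v <- truncated_cone_volume(357, 803, 366)
  expect_lt(abs(v / slab_oracle(357, 803, 366) - 1), 1e-3)
  expect_error(truncated_cone_volume(-1, 2, 3), "non-negative")
})

test_that("measure_hole on a truth mask reproduces the analytic parameters", {
  spec <- test_spec()
  ph <- generate_phantom(spec)
  sf <- list(rpe = surface_map(matrix(400, 120, 25), "RPE"),
             ilm = surface_map(matrix(100, 120, 25), "ILM"))
  rep <- measure_hole(ph$truth, sf$rpe, sf$ilm)
  tr <- ph$truth_params
  expect_lte(abs(rep$ba_max - tr$ba_max), 50)
  expect_lte(abs(rep$ma_min - tr$ma_min), 50)
  expect_lt(abs(rep$volume / tr$volume - 1), 0.05)
  expect_lt(abs(rep$surface_area / tr$surface_area - 1), 0.05)
  expect_lte(rep$ma_min, rep$ma_max)
  expect_lte(rep$ba_min, rep$ba_max)
  expect_gte(rep$ma_height, 0.2 * rep$hole_height - 1e-9)
  expect_lte(rep$ma_height, 0.9 * rep$hole_height + 1e-9)
  # section-area integral consistency with the voxel volume
  expect_lt(abs(sum(rep$sections$area_um2) * 5 / rep$volume - 1), 0.02)
  expect_s3_class(as.data.frame(rep), "data.frame")
})
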