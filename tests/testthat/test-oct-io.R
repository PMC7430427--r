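test_that("voxel spacing and volume constructors validate their inputs", {
  sp <- voxel_spacing(5.47, 3.87, 30)
  expect_s3_class(sp, "voxel_spacing")
  expect_error(voxel_spacing(0, 1, 1), "positive")
  expect_error(oct_volume(array(0, c(4, 4)), sp), "3D")
  expect_error(oct_volume(array(-1, c(4, 4, 4)), sp), "non-negative")
  expect_error(oct_volume(array(0, c(1, 4, 4)), sp), "at least 2")
})

test_that("TIFF stack round trip is bit-exact and carries metadata", {
  set.seed(1)
  arr <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  vol <- oct_volume(arr, voxel_spacing(5.47, 3.87, 30), source_id = "rt")
  dir <- withr::local_tempdir()
  write_tiff_stack(vol, dir)
  back <- read_tiff_stack(dir)
  expect_identical(back$intensities, vol$intensities + 0)
  expect_equal(unclass(back$spacing), unclass(vol$spacing), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$source_id, "rt")
  # 16-bit values survive too
  arr16 <- array(sample(0:60000, 4 * 4 * 2, replace = TRUE), dim = c(4, 4, 2))
  v16 <- oct_volume(arr16, voxel_spacing(5, 5, 30))
  d16 <- withr::local_tempdir()
  write_tiff_stack(v16, d16, bits = 16L)
  expect_identical(read_tiff_stack(d16)$intensities, arr16 + 0)
})

test_that("two identical zero images give a zero volume of the right shape", {
  dir <- withr::local_tempdir()
  vol <- oct_volume(array(0, c(8, 8, 2)), voxel_spacing(5, 5, 30))
  write_tiff_stack(vol, dir)
  back <- read_tiff_stack(dir, voxel_spacing(5, 5, 30))
  expect_equal(dim(back$intensities), c(8L, 8L, 2L))
  expect_true(all(back$intensities == 0))
})

test_that("mismatched B-scan dimensions are rejected with the file named", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 10, 12), file.path(dir, "a.tiff"),
                  bits.per.sample = 8)
  tiff::writeTIFF(matrix(0, 10, 8), file.path(dir, "b.tiff"),
                  bits.per.sample = 8)
  expect_error(read_tiff_stack(dir, voxel_spacing(5, 5, 30)),
               "b\\.tiff")
})

test_that("non-grayscale and unreadable files are rejected by name", {
  dir <- withr::local_tempdir()
  rgb <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  tiff::writeTIFF(rgb, file.path(dir, "rgb.tiff"), bits.per.sample = 8)
  tiff::writeTIFF(matrix(0, 4, 4), file.path(dir, "ok.tiff"),
                  bits.per.sample = 8)
  expect_error(read_tiff_stack(dir, voxel_spacing(5, 5, 30)), "rgb\\.tiff")
  dir2 <- withr::local_tempdir()
  writeLines("not a tiff", file.path(dir2, "bad.tiff"))
  tiff::writeTIFF(matrix(0, 4, 4), file.path(dir2, "ok.tiff"),
                  bits.per.sample = 8)
  expect_error(read_tiff_stack(dir2, voxel_spacing(5, 5, 30)), "bad\\.tiff")
})

test_that("missing dz metadata falls back to 30 um with a warning", {
  dir <- withr::local_tempdir()
  for (f in c("a.tiff", "b.tiff"))
    tiff::writeTIFF(matrix(0.5, 6, 6), file.path(dir, f), bits.per.sample = 8)
  writeLines(c("dx_um=5.47", "dy_um=3.87"), file.path(dir, "metadata.txt"))
  expect_warning(vol <- read_tiff_stack(dir), "30")
  expect_equal(unname(vol$spacing[3]), 30)
})

test_that("surface CSV round trips", {
  m <- matrix(runif(5 * 3, 100, 400), 5, 3)
  sm <- surface_map(m, "RPE")
  f <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(sm, f)
  back <- read_surface_csv(f, "RPE")
  expect_equal(back$y_um, m)
})

test_that("dice behaves as an overlap measure", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 2)); b[1, 1, 1] <- TRUE
  expect_equal(dice(a, b), 2 * 1 / (2 + 1))
  expect_error(dice(a, array(FALSE, c(3, 4, 2))), "dimensions")
})
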