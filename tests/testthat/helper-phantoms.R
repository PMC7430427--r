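# Shared phantom factories and independent oracles.
# Desk-scale test geometry: 120 x 96 x 25-27 voxels at (10, 5, 25) um,
# hole diameters 200-550 um. The phantom_spec() *defaults* stay at the
# clinical protocol geometry; tests use these smaller grids.

test_spacing <- function() voxel_spacing(10, 5, 25)

spec_with <- function(defaults, overrides) {
  do.call(phantom_spec, utils::modifyList(defaults, overrides))
}

# hourglass with tilt and distinct meridians: the general-purpose phantom
test_spec <- function(...) {
  spec_with(list(nx = 120L, ny = 96L, nz = 25L, spacing = test_spacing(),
                 ilm_um = 100, rpe_um = 400,
                 base = c(250, 210, 20), waist = c(150, 120, 10),
                 top = c(180, 150, 30), waist_frac = 0.5,
                 tilt_um = c(60, 40)), list(...))
}

# template for jittered recovery suites (fits the footprint under jitter)
suite_spec <- function(...) {
  spec_with(list(nx = 120L, ny = 96L, nz = 27L, spacing = test_spacing(),
                 ilm_um = 100, rpe_um = 400,
                 base = c(240, 170, 0), waist = c(150, 105, 0),
                 top = c(175, 125, 0), waist_frac = 0.5,
                 tilt_um = c(55, 35), speckle_s = 0.05), list(...))
}

# small phantom for unit-level level-set tests
tiny_spec <- function(...) {
  spec_with(list(nx = 80L, ny = 72L, nz = 17L, spacing = test_spacing(),
                 ilm_um = 80, rpe_um = 300,
                 base = c(160, 130, 0), waist = c(100, 80, 0),
                 top = c(120, 95, 0), waist_frac = 0.5,
                 tilt_um = c(0, 0)), list(...))
}

cylinder_spec <- function(r = 200, ...) {
  spec_with(list(nx = 120L, ny = 96L, nz = 25L, spacing = test_spacing(),
                 ilm_um = 100, rpe_um = 400,
                 base = c(r, r, 0), waist = c(r, r, 0), top = c(r, r, 0),
                 waist_frac = 0.5, tilt_um = c(0, 0)), list(...))
}

# digitise a solid on an isotropic grid (centre-in-solid rule)
digitise <- function(fun, dims, sp = c(5, 5, 5)) {
  arr <- array(FALSE, dims)
  x <- (seq_len(dims[1]) - 1) * sp[1]
  for (k in seq_len(dims[3])) {
    z <- (k - 1) * sp[3]
    for (j in seq_len(dims[2])) {
      arr[, j, k] <- fun(x, (j - 1) * sp[2], z)
    }
  }
  hole_mask(arr, voxel_spacing(sp[1], sp[2], sp[3]))
}

# brute-force Feret oracle: projection extents at fine angular steps
feret_bruteforce <- function(pts, step_deg = 0.1) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ext <- vapply(th, function(a) {
    p <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  list(feret_min = min(ext), feret_max = max(ext),
       angle_min = th[which.min(ext)] * 180 / pi,
       angle_max = th[which.max(ext)] * 180 / pi)
}

# seeded random convex polygon (convex hull of random points)
random_convex_polygon <- function(n_pts = 12, scale = 100) {
  pts <- cbind(runif(n_pts, 0, scale), runif(n_pts, 0, scale))
  pts[grDevices::chull(pts), , drop = FALSE]
}

angdiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# fit one phantom end-to-end and return measured coefficients + dice
fit_phantom <- function(spec) {
  ph <- generate_phantom(spec)
  fit <- macular_hole(ph$volume)
  list(fit = fit, coef = coef(fit), truth = ph$truth_params,
       dice = dice(fit$mask, ph$truth))
}
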