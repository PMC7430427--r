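#' Estimate the RPE and ILM reference surfaces of an OCT volume
#'
#' Per A-scan column the RPE is located as the dominant bright band after
#' Gaussian smoothing along depth; the reported RPE position is the *upper
#' edge* of the band (the half-peak crossing walking up from the peak),
#' which is the base plane of a full-thickness hole. The ILM is the first
#' depth, from the vitreous side, at which the smoothed intensity exceeds
#' a fraction of that column's peak. Columns inside the hole opening have
#' no retina above the RPE, so their raw ILM detection collapses onto the
#' RPE; such columns (inter-surface distance below half the median retinal
#' thickness) are treated as missing and the ILM is inpainted from the
#' surrounding columns, giving the membrane that spans the hole. Both maps
#' are median-filtered across the footprint.
#'
#' @param volume an [oct_volume()].
#' @param smooth_um Gaussian depth-smoothing scale in micrometres.
#' @param ilm_frac fraction of the column peak that defines the ILM
#'   crossing (default 0.5).
#' @param rpe_edge_frac fraction of the peak defining the RPE upper edge.
#' @param max_undetectable maximum tolerated fraction of columns with no
#'   detectable band before the estimate is rejected.
#' @param median_px half-width in pixels of the footprint median filter.
#' @param opening_um half-width (um) of the grey-opening window used to
#'   reject hole-notch artefacts in the ILM map; must exceed the en-face
#'   radius of the hole opening at the ILM.
#' @return list with elements `rpe` and `ilm`, both [surface_map()]s.
#' @export
estimate_surfaces <- function(volume, smooth_um = 8, ilm_frac = 0.5,
                              rpe_edge_frac = 0.5, max_undetectable = 0.05,
                              median_px = 1L, opening_um = 250) {
  stopifnot(inherits(volume, "oct_volume"))
  I <- volume$intensities
  d <- dim(I); nx <- d[1]; ny <- d[2]; nz <- d[3]
  sp <- volume$spacing; dy <- sp[2]
  rng <- range(I)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2])))
    stop("constant-intensity volume: no retinal band detectable")
  G <- gauss3_cpp(I, dim(I), 0, smooth_um / dy, 0)

  rpe_idx <- matrix(NA_real_, nx, nz)
  ilm_idx <- matrix(NA_real_, nx, nz)
  ret_ref <- matrix(NA_real_, nx, nz)
  undetectable <- matrix(FALSE, nx, nz)
  contrast_floor <- 0.05 * (rng[2] - rng[1])
  pk_all <- matrix(NA_integer_, nx, nz)
  pkv_all <- matrix(NA_real_, nx, nz)
  base_all <- matrix(NA_real_, nx, nz)
  # pass 1: peak, ILM crossing and per-column retina reference level
  for (k in seq_len(nz)) {
    g <- G[, , k]                       # nx x ny
    pk <- max.col(g, ties.method = "first")
    pkv <- g[cbind(seq_len(nx), pk)]
    base <- apply(g, 1, min)
    pk_all[, k] <- pk; pkv_all[, k] <- pkv; base_all[, k] <- base
    for (i in seq_len(nx)) {
      if (pkv[i] - base[i] < contrast_floor) { undetectable[i, k] <- TRUE; next }
      thr_ilm <- base[i] + ilm_frac * (pkv[i] - base[i])
      ilm_i <- which(g[i, ] >= thr_ilm)[1]
      ilm_idx[i, k] <- ilm_i
      # dimmest level between the ILM crossing and the RPE peak: the
      # retina plateau in normal columns, near-peak in hole columns
      lo <- min(ilm_i, pk[i] - 1L)
      ret_ref[i, k] <- min(g[i, lo:max(lo, pk[i] - 1L)])
    }
  }
  # pass 2: RPE band upper edge, thresholded against a footprint-global
  # retina level (hole columns have no retina of their own to reference;
  # a per-column reference would bias their RPE a voxel deep and stagger
  # the base plane across rows)
  med_ret <- median(ret_ref, na.rm = TRUE)
  for (k in seq_len(nz)) {
    g <- G[, , k]
    for (i in seq_len(nx)) {
      if (undetectable[i, k]) next
      thr_rpe <- med_ret + rpe_edge_frac * (pkv_all[i, k] - med_ret)
      thr_rpe <- min(thr_rpe,
                     base_all[i, k] + 0.9 * (pkv_all[i, k] - base_all[i, k]))
      j <- pk_all[i, k]
      while (j > 1 && g[i, j - 1] >= thr_rpe) j <- j - 1
      rpe_idx[i, k] <- j
    }
  }
  n_bad <- sum(undetectable)
  if (n_bad > max_undetectable * nx * nz) {
    bad <- which(undetectable, arr.ind = TRUE)
    stop(sprintf(paste0("no detectable retinal band in %d of %d columns ",
                        "(> %.0f%% allowed); first offenders (x,z): %s"),
                 n_bad, nx * nz, 100 * max_undetectable,
                 paste(utils::head(apply(bad, 1, paste, collapse = ","), 5),
                       collapse = "; ")))
  }
  rpe_idx <- inpaint_map(rpe_idx)
  ilm_idx <- inpaint_map(ilm_idx)

  # hole-opening columns: ILM collapsed onto (or towards) the RPE; treat as
  # missing and span the membrane across the opening by inpainting
  thick <- rpe_idx - ilm_idx
  med_thick <- median(thick[thick > 0], na.rm = TRUE)
  ilm_idx[thick < 0.75 * med_thick] <- NA
  ilm_idx <- inpaint_map(ilm_idx)
  # columns whose hole notch starts just below the membrane pass the
  # thickness test but are still detected too deep. The error is strictly
  # one-sided (a notch can only push the detection down), so a grey-scale
  # opening with a window wider than the hole opening removes the deep bump
  # while leaving ramps (tilted retina) untouched.
  ilm_idx <- grey_open_map(ilm_idx,
                           max(1L, ceiling(opening_um / sp[1])),
                           max(1L, ceiling(opening_um / sp[3])))

  rpe_idx <- median_filter2(rpe_idx, median_px)
  ilm_idx <- median_filter2(ilm_idx, median_px)
  ilm_idx <- pmin(ilm_idx, rpe_idx - 1)   # ILM strictly above RPE
  list(rpe = surface_map((rpe_idx - 1) * dy, "RPE"),
       ilm = surface_map((ilm_idx - 1) * dy, "ILM"))
}

# fill NAs by iterative neighbour averaging (simple harmonic inpainting)
inpaint_map <- function(m, max_iter = 500L) {
  bad <- is.na(m)
  if (!any(bad)) return(m)
  if (all(bad)) stop("cannot inpaint: no valid surface columns")
  m[bad] <- mean(m, na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    nb <- neighbour_mean(m)
    new <- ifelse(bad, nb, m)
    if (max(abs(new - m)) < 1e-6) { m <- new; break }
    m <- new
  }
  m
}

neighbour_mean <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  s[-1, ] <- s[-1, ] + m[-nr, ]; n[-1, ] <- n[-1, ] + 1
  s[-nr, ] <- s[-nr, ] + m[-1, ]; n[-nr, ] <- n[-nr, ] + 1
  s[, -1] <- s[, -1] + m[, -nc]; n[, -1] <- n[, -1] + 1
  s[, -nc] <- s[, -nc] + m[, -1]; n[, -nc] <- n[, -nc] + 1
  s / n
}

# grey-scale opening (min filter then max filter) with a rectangular
# window of half-widths rx (rows) and rz (cols); separable
grey_open_map <- function(m, rx, rz) {
  runfilt <- function(v, r, fun) {
    n <- length(v)
    vapply(seq_len(n), function(i) fun(v[max(1, i - r):min(n, i + r)]),
           numeric(1))
  }
  pass <- function(m, fun) {
    m <- t(apply(m, 1, runfilt, r = rz, fun = fun))
    apply(m, 2, runfilt, r = rx, fun = fun)
  }
  pass(pass(m, min), max)
}

median_filter2 <- function(m, r = 1L) {
  if (r < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    i0 <- max(1, i - r); i1 <- min(nr, i + r)
    for (j in seq_len(nc)) {
      j0 <- max(1, j - r); j1 <- min(nc, j + r)
      out[i, j] <- median(m[i0:i1, j0:j1])
    }
  }
  out
}

#' Flatten an OCT volume to its RPE surface
#'
#' Shifts every A-scan column along depth by a whole number of voxels so
#' the RPE comes to a common level, making RPE-parallel planes grid
#' slices. Whole-voxel shifts keep intensities bit-faithful. If a shift
#' would push tissue outside the grid the volume is padded with a declared
#' background value rather than cropped.
#'
#' @param volume an [oct_volume()].
#' @param rpe RPE [surface_map()] estimated on the same volume.
#' @param ilm optional ILM [surface_map()]; returned shifted into the
#'   flattened frame.
#' @param background pad value (default the volume minimum).
#' @return list with `volume` (flattened [oct_volume()]), `ilm` (shifted
#'   map or `NULL`), `rpe_level_um` (the common RPE depth), `shifts`
#'   (voxel shift matrix, for [unflatten_volume()]) and `orig_ny`.
#' @export
flatten_volume <- function(volume, rpe, ilm = NULL, background = NULL) {
  stopifnot(inherits(volume, "oct_volume"), inherits(rpe, "surface_map"))
  I <- volume$intensities
  d <- dim(I); nx <- d[1]; ny <- d[2]; nz <- d[3]
  dy <- volume$spacing[2]
  if (!all(dim(rpe$y_um) == c(nx, nz)))
    stop("surface footprint does not match the volume")
  if (is.null(background)) background <- min(I)
  rpe_row <- round(rpe$y_um / dy) + 1L
  target <- round(median(rpe_row))
  shifts <- target - rpe_row             # positive: move column down
  ny_new <- ny
  pad_top <- max(0L, max(shifts))        # content pushed below the grid?
  pad_bot <- max(0L, -min(shifts))
  # grow only when content would be lost
  need_bot <- max(0L, max(shifts))       # shifting down by s loses bottom s rows
  need_top <- max(0L, -min(shifts))
  ny_new <- ny + need_bot + need_top
  off <- need_top                        # rows added on top
  out <- array(background, dim = c(nx, ny_new, nz))
  for (k in seq_len(nz)) for (i in seq_len(nx)) {
    s <- shifts[i, k]
    out[i, seq_len(ny) + s + off, k] <- I[i, , k]
  }
  flat <- oct_volume(out, volume$spacing,
                     source_id = paste0(volume$source_id, "_flat"))
  ilm_flat <- NULL
  if (!is.null(ilm)) {
    ilm_flat <- surface_map(ilm$y_um + (shifts + off) * dy, "ILM")
  }
  list(volume = flat, ilm = ilm_flat,
       rpe_level_um = (target - 1L + off) * dy,
       shifts = shifts, offset = off, orig_ny = ny)
}

#' Undo [flatten_volume()]
#'
#' Restores the original voxel values exactly (whole-voxel shifts are
#' lossless).
#'
#' @param flat the list returned by [flatten_volume()], or a flattened
#'   [oct_volume()] together with `shifts`, `offset`, `orig_ny`.
#' @param shifts,offset,orig_ny bookkeeping from [flatten_volume()]
#'   (taken from `flat` when it is the full list).
#' @return the original [oct_volume()].
#' @export
unflatten_volume <- function(flat, shifts = NULL, offset = NULL, orig_ny = NULL) {
  if (is.list(flat) && !inherits(flat, "oct_volume")) {
    shifts <- flat$shifts; offset <- flat$offset; orig_ny <- flat$orig_ny
    flat <- flat$volume
  }
  I <- flat$intensities
  d <- dim(I); nx <- d[1]; nz <- d[3]
  out <- array(0, dim = c(nx, orig_ny, nz))
  for (k in seq_len(nz)) for (i in seq_len(nx)) {
    s <- shifts[i, k]
    out[i, , k] <- I[i, seq_len(orig_ny) + s + offset, k]
  }
  oct_volume(out, flat$spacing,
             source_id = sub("_flat$", "", flat$source_id))
}
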