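#' Parameters of the curvature-based surface cut
#'
#' @param window_um Gaussian scale (um) used to smooth the mask before
#'   curvature estimation (roughly one voxel per axis by default when
#'   `NULL`).
#' @param curvature_quantile rim voxels must exceed this quantile of the
#'   boundary curvature magnitude.
#' @param ilm_tol_vox rim voxels must lie within this many voxels (along
#'   Y) of the ILM surface.
#' @return An object of class `cut_params`.
#' @export
cut_params <- function(window_um = NULL, curvature_quantile = 0.9,
                       ilm_tol_vox = 2L) {
  if (!is.null(window_um) && window_um <= 0) stop("window_um must be positive")
  structure(list(window_um = window_um,
                 curvature_quantile = curvature_quantile,
                 ilm_tol_vox = as.integer(ilm_tol_vox)),
            class = "cut_params")
}

#' Separate the macular hole from the vitreous by a curvature-based cut
#'
#' The hole and the vitreous are both hypo-reflective and contiguous
#' through the hole opening, so the level-set region routinely leaks above
#' the ILM. This cut computes the mean curvature of the (smoothed) region
#' surface, identifies the high-curvature rim ring where the region
#' crosses the ILM, spans a cap surface across the rim (harmonic
#' inpainting of the rim heights over the hole footprint, clamped to the
#' ILM), and discards everything above the cap; the region is clipped
#' analogously at the RPE plane. The result is the closed hole-only mask
#' between ILM and RPE. If the region lies entirely below the ILM the mask
#' is returned unchanged with a `notice` attribute. When several
#' components survive the cut, the one containing the region centroid is
#' kept (largest as fallback). The operation is idempotent.
#'
#' @param region a [hole_mask()] (possibly leaking into the vitreous).
#' @param rpe,ilm [surface_map()]s on the same grid.
#' @param cut a [cut_params()].
#' @return a [hole_mask()]; attribute `rim_voxels` gives the rim size,
#'   attribute `notice` is set when no cut was needed.
#' @export
curvature_surface_cut <- function(region, rpe, ilm, cut = cut_params()) {
  stopifnot(inherits(region, "hole_mask"))
  mask <- region$voxels
  if (!any(mask)) stop("empty region mask")
  sp <- region$spacing; dy <- sp[2]
  d <- dim(mask)
  ycent <- array(rep((seq_len(d[2]) - 1) * dy, each = d[1]), dim = d)
  ilm_arr <- array(0, dim = d); rpe_arr <- array(0, dim = d)
  for (j in seq_len(d[2])) { ilm_arr[, j, ] <- ilm$y_um; rpe_arr[, j, ] <- rpe$y_um }

  above <- mask & (ycent < ilm_arr - 1.5 * dy)
  if (!any(above)) {
    out <- hole_mask(mask, sp, region$source_id)
    attr(out, "notice") <- "region entirely below the ILM; no cut applied"
    return(out)
  }

  # boundary voxels and their mean curvature on the smoothed region surface
  eroded <- morph3_cpp(mask, d, 1L, "erode")
  boundary <- mask & !eroded
  w <- cut$window_um
  sx <- if (is.null(w)) 1 else w / sp[1]
  sy <- if (is.null(w)) 1 else w / sp[2]
  sz <- if (is.null(w)) 1 else w / sp[3]
  u <- gauss3_cpp(array(as.double(mask), dim = d), d, sx, sy, sz)
  kap <- abs(mean_curvature_cpp(u, d, sp))
  thr <- quantile(kap[boundary], cut$curvature_quantile, names = FALSE)
  rim <- boundary & abs(ycent - ilm_arr) <= cut$ilm_tol_vox * dy & kap >= thr

  # columns of the hole opening: the region is contiguous across the ILM
  # (mask present just below and just above the membrane); elsewhere any
  # supra-ILM mask is pure vitreous leak and is cut at the ILM itself
  below_flag <- apply(mask & ycent >= ilm_arr & ycent < ilm_arr + 3 * dy,
                      c(1, 3), any)
  above_flag <- apply(mask & ycent < ilm_arr & ycent >= ilm_arr - 3 * dy,
                      c(1, 3), any)
  opening <- below_flag & above_flag

  # cap surface spanning the rim, inpainted over the opening footprint
  cap <- ilm$y_um
  if (any(rim) && any(opening)) {
    rim_cap <- matrix(NA_real_, d[1], d[3])
    idx <- which(rim, arr.ind = TRUE)
    ys <- (idx[, 2] - 1) * dy
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; k <- idx[r, 3]
      rim_cap[i, k] <- if (is.na(rim_cap[i, k])) ys[r] else min(rim_cap[i, k], ys[r])
    }
    rim_cap <- inpaint_map(rim_cap)
    # rim voxels sit on the mask shoulder, half a voxel or so deep; the
    # inpainted ILM is accurate away from strong leak. Take the shallower
    # of the two over the opening.
    cap[opening] <- pmin(rim_cap[opening], ilm$y_um[opening])
  }
  cap <- pmax(cap, ilm$y_um - dy)        # one-sided clamp near the membrane
  cap <- pmin(cap, rpe$y_um - dy)

  cap_arr <- array(0, dim = d)
  for (j in seq_len(d[2])) cap_arr[, j, ] <- cap
  keep <- mask & (ycent >= cap_arr - 0.5 * dy) & (ycent < rpe_arr - 0.5 * dy)
  if (!any(keep)) stop("surface cut removed the whole region; check surfaces")

  # retain the component that contains the region centroid (largest otherwise)
  lab <- label6_cpp(keep, d)
  sizes <- tabulate(lab[keep])
  if (length(sizes) > 1L) {
    cen <- round(colMeans(which(keep, arr.ind = TRUE)))
    cl <- lab[cen[1], cen[2], cen[3]]
    if (cl == 0L) cl <- which.max(sizes)
    keep <- keep & (lab == cl)
  }
  out <- hole_mask(keep, sp, region$source_id)
  attr(out, "rim_voxels") <- sum(rim)
  out
}
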