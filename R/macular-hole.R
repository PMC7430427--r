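#' Segment and measure a macular hole in an OCT volume
#'
#' The central entry point: takes an OCT volume (or a folder of TIFF
#' B-scans), estimates the RPE and ILM reference surfaces, flattens the
#' volume to the RPE, segments the hole with the multiscale LGDF level
#' set, separates it from the vitreous with the curvature-based surface
#' cut, and derives the full morphometric parameter set.
#'
#' @param x an [oct_volume()], or a folder path readable by
#'   [read_tiff_stack()].
#' @param spacing optional [voxel_spacing()] when `x` is a path.
#' @param params a [level_set_params()]; defaults are derived from the
#'   volume's spacing.
#' @param cut a [cut_params()].
#' @param surfaces optional precomputed list with `rpe` and `ilm`
#'   [surface_map()]s (skips estimation).
#' @return An object of class `macular_hole` with components `report`
#'   (an `mh_report`), `mask` (hole mask in the original frame),
#'   `mask_flat`, `surfaces`, `flat` (flattening bookkeeping), `params`,
#'   `volume_dim`, `spacing`, `source_id`, `call`. Methods: `print`,
#'   `summary`, `coef` (named numeric parameter vector), `plot`.
#' @examples
#' \donttest{
#' spec <- phantom_spec(nx = 96, ny = 80, nz = 21,
#'                      spacing = voxel_spacing(10, 5, 25),
#'                      ilm_um = 100, rpe_um = 280,
#'                      base = c(220, 180, 0), waist = c(140, 110, 0),
#'                      top = c(160, 130, 0), waist_frac = 0.5,
#'                      tilt_um = c(40, 30))
#' ph <- generate_phantom(spec)
#' fit <- macular_hole(ph$volume)
#' coef(fit)["ma_min"]
#' }
#' @export
macular_hole <- function(x, spacing = NULL, params = NULL,
                         cut = cut_params(), surfaces = NULL) {
  cl <- match.call()
  volume <- if (is.character(x)) read_tiff_stack(x, spacing) else x
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(params)) params <- level_set_params(volume$spacing)
  if (is.null(surfaces)) surfaces <- estimate_surfaces(volume)
  fl <- flatten_volume(volume, surfaces$rpe, ilm = surfaces$ilm)
  rpe_flat <- surface_map(matrix(fl$rpe_level_um, nrow(surfaces$rpe$y_um),
                                 ncol(surfaces$rpe$y_um)), "RPE")
  raw <- multiscale_segment(fl$volume, params, rpe_flat, fl$ilm)
  mask_flat <- curvature_surface_cut(raw, rpe_flat, fl$ilm, cut)
  report <- measure_hole(mask_flat, fl$rpe_level_um, fl$ilm)
  report$source_id <- volume$source_id
  # mask back in the original (un-flattened) frame
  mvol <- oct_volume(array(as.double(mask_flat$voxels), dim(mask_flat$voxels)) + 0,
                     volume$spacing, volume$source_id)
  morig <- unflatten_volume(mvol, fl$shifts, fl$offset, fl$orig_ny)
  structure(list(report = report,
                 mask = hole_mask(morig$intensities > 0.5, volume$spacing,
                                  volume$source_id),
                 mask_flat = mask_flat,
                 surfaces = surfaces,
                 flat = fl[c("rpe_level_um", "shifts", "offset", "orig_ny")],
                 params = params,
                 scale_log = attr(raw, "scale_log"),
                 volume_dim = dim(volume$intensities),
                 spacing = volume$spacing,
                 source_id = volume$source_id, call = cl),
            class = "macular_hole")
}

#' @export
print.macular_hole <- function(x, ...) {
  cat("Automated 3D macular hole segmentation\n")
  cat(sprintf("  volume '%s': %s voxels @ (%.3g, %.3g, %.3g) um\n",
              x$source_id, paste(x$volume_dim, collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  it <- vapply(x$scale_log, function(s) s$iterations, numeric(1))
  sc <- vapply(x$scale_log, function(s) s$scale, numeric(1))
  cat(sprintf("  level-set iterations: %s\n",
              paste(sprintf("%d@1/%d", it, sc), collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' @export
summary.macular_hole <- function(object, ...) {
  print(object)
  s <- object$report$sections
  cat(sprintf("\n%d RPE-parallel sections, heights %.0f-%.0f um; area range %.3g-%.3g um^2\n",
              nrow(s), min(s$height_um), max(s$height_um),
              min(s$area_um2), max(s$area_um2)))
  invisible(object)
}

#' @export
coef.macular_hole <- function(object, ...) {
  r <- object$report
  num <- vapply(r[setdiff(names(r), c("sections", "ivts_class", "source_id",
                                      "full_thickness"))],
                as.numeric, numeric(1))
  num
}

#' @export
plot.macular_hole <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  foot <- apply(x$mask_flat$voxels, c(1, 3), sum) * x$spacing[2]
  image(x = (seq_len(nrow(foot)) - 1) * x$spacing[1],
        y = (seq_len(ncol(foot)) - 1) * x$spacing[3],
        z = foot, col = gray(seq(1, 0, length.out = 64)),
        xlab = "X (um)", ylab = "Z (um)", asp = 1)
  title("en-face hole thickness")
  s <- x$report$sections
  plot(s$area_um2 / 1e3, s$height_um, type = "l",
       xlab = expression(paste("section area (", 10^3, " ", mu, m^2, ")")),
       ylab = "height above RPE (um)")
  abline(h = c(0.2, 0.9) * x$report$hole_height, lty = 3)
  abline(h = x$report$ma_height, lty = 2)
  title("area profile (MA dashed)")
  invisible(x)
}
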