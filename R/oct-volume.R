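#' Voxel spacing of an OCT volume
#'
#' Physical size of one voxel along each axis, in micrometres. X runs
#' across a B-scan (horizontal), Y is depth within a B-scan (vitreous
#' towards RPE, increasing downward), Z steps across B-scans. OCT volumes
#' are strongly anisotropic: the B-scan line spacing (`dz`) is typically
#' five to six times the in-plane pixel pitch.
#'
#' @param dx,dy,dz micrometres per voxel along X, Y and Z. All must be
#'   strictly positive.
#' @return An object of class `voxel_spacing`: a named numeric vector
#'   `c(dx, dy, dz)`.
#' @examples
#' voxel_spacing(5.47, 3.87, 30)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("voxel spacing must be finite and strictly positive")
  structure(s, class = "voxel_spacing")
}

as_spacing <- function(x) {
  if (inherits(x, "voxel_spacing")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(voxel_spacing(x[1], x[2], x[3]))
  stop("expected a voxel_spacing or a numeric vector of length 3")
}

#' OCT intensity volume
#'
#' A 3D grid of non-negative intensities indexed `[x, y, z]` with physical
#' voxel spacing. Voxel `[i, j, k]` (1-based in R) has its centre at
#' physical position `((i-1) dx, (j-1) dy, (k-1) dz)` micrometres, with the
#' origin at the top-left corner of the first B-scan and Y increasing with
#' depth.
#'
#' @param intensities numeric 3D array, dimensions `(nx, ny, nz)`, all >= 2.
#' @param spacing a [voxel_spacing()] (or numeric length-3 vector).
#' @param source_id free-text identifier carried through reports.
#' @return An object of class `oct_volume` with elements `intensities`,
#'   `spacing`, `source_id`.
#' @export
oct_volume <- function(intensities, spacing, source_id = "volume") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 2L))
    stop("volume must be at least 2 voxels along every axis")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  structure(list(intensities = intensities, spacing = as_spacing(spacing),
                 source_id = as.character(source_id)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("OCT volume '%s': %d x %d x %d voxels (X x Y x Z)\n",
              x$source_id, d[1], d[2], d[3]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g um; footprint %.0f x %.0f um, depth %.0f um\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              (d[1] - 1) * x$spacing[1], (d[3] - 1) * x$spacing[3],
              (d[2] - 1) * x$spacing[2]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensities)

#' Binary hole mask aligned to an OCT volume
#'
#' @param voxels logical 3D array, same dimensions as its source volume.
#' @param spacing a [voxel_spacing()].
#' @param source_id identifier, usually inherited from the volume.
#' @return An object of class `hole_mask`.
#' @export
hole_mask <- function(voxels, spacing, source_id = "mask") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  structure(list(voxels = voxels, spacing = as_spacing(spacing),
                 source_id = as.character(source_id)),
            class = "hole_mask")
}

#' @export
print.hole_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Hole mask '%s': %d x %d x %d voxels, %d set (%.2f%%)\n",
              x$source_id, d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

#' @export
dim.hole_mask <- function(x) dim(x$voxels)

#' Retinal reference surface (RPE or ILM) as a height map
#'
#' Stores, for every `(x, z)` footprint position, the Y depth (micrometres)
#' of a retinal surface. By the depth convention the ILM lies above the RPE,
#' i.e. `ilm$y_um < rpe$y_um` everywhere.
#'
#' @param y_um numeric matrix `(nx, nz)` of Y positions in micrometres.
#' @param kind `"RPE"` or `"ILM"`.
#' @return An object of class `surface_map`.
#' @export
surface_map <- function(y_um, kind = c("RPE", "ILM")) {
  kind <- match.arg(kind)
  if (!is.matrix(y_um)) stop("y_um must be a matrix (nx x nz)")
  if (any(!is.finite(y_um))) stop("surface heights must be finite")
  structure(list(y_um = y_um, kind = kind), class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("%s surface map %d x %d, depth range [%.1f, %.1f] um\n",
              x$kind, nrow(x$y_um), ncol(x$y_um), min(x$y_um), max(x$y_um)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# TIFF stack I/O
# ---------------------------------------------------------------------------

#' Read an OCT volume from a folder of grayscale TIFF B-scans
#'
#' One uncompressed (or losslessly compressed) grayscale TIFF per B-scan;
#' lexicographic filename order defines the Z order. All images must share
#' the same dimensions. Pixel values are preserved bit-exactly.
#'
#' If `spacing` is `NULL` a sidecar `metadata.txt` (key=value lines with
#' `dx_um`, `dy_um`, `dz_um` and optionally `source_id`) is read from the
#' folder; a missing `dz_um` falls back to 30 um with a warning, the
#' conventional line spacing of the high-density horizontal protocol.
#'
#' @param folder path containing at least two `.tif`/`.tiff` files.
#' @param spacing a [voxel_spacing()], or `NULL` to read the sidecar.
#' @return An [oct_volume()].
#' @export
read_tiff_stack <- function(folder, spacing = NULL) {
  if (!dir.exists(folder)) stop("folder does not exist: ", folder)
  files <- sort(list.files(folder, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) < 2L)
    stop("folder must contain at least two TIFF files: ", folder)
  if (is.null(spacing)) spacing <- read_spacing_metadata(folder)
  slices <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(tiff::readTIFF(files[i], as.is = TRUE),
                    error = function(e) stop("cannot read TIFF '",
                                             basename(files[i]), "': ",
                                             conditionMessage(e)))
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] == 1L) img <- img[, , 1]
      else stop("non-grayscale TIFF (", dim(img)[3], " channels): ",
                basename(files[i]))
    }
    slices[[i]] <- img
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop(sprintf("B-scan dimension mismatch: '%s' is %dx%d but '%s' is %dx%d",
                 basename(files[1]), dims[2, 1], dims[1, 1],
                 basename(files[bad]), dims[2, bad], dims[1, bad]))
  }
  # readTIFF returns [row = y, col = x]; store as [x, y, z]
  nx <- dims[2, 1]; ny <- dims[1, 1]; nz <- length(files)
  vol <- array(0, dim = c(nx, ny, nz))
  for (i in seq_len(nz)) vol[, , i] <- t(slices[[i]])
  sid <- attr(spacing, "source_id")
  oct_volume(vol, spacing, source_id = if (is.null(sid)) basename(folder) else sid)
}

read_spacing_metadata <- function(folder) {
  mf <- file.path(folder, "metadata.txt")
  kv <- list()
  if (file.exists(mf)) {
    lines <- readLines(mf, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) kv[[trimws(parts[1])]] <- trimws(parts[2])
    }
  }
  dx <- as.numeric(kv[["dx_um"]] %||% NA)
  dy <- as.numeric(kv[["dy_um"]] %||% NA)
  dz <- as.numeric(kv[["dz_um"]] %||% NA)
  if (is.na(dx) || is.na(dy))
    stop("no spacing given and no usable metadata.txt (dx_um, dy_um) in ", folder)
  if (is.na(dz)) {
    warning("dz_um absent from metadata; assuming 30 um line spacing")
    dz <- 30
  }
  sp <- voxel_spacing(dx, dy, dz)
  attr(sp, "source_id") <- kv[["source_id"]]
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume or mask as a folder of grayscale TIFF B-scans
#'
#' Integer intensities are written bit-exactly (8- or 16-bit); masks are
#' written as 0/255. A `metadata.txt` sidecar with the voxel spacing is
#' written alongside.
#'
#' @param x an [oct_volume()] or [hole_mask()].
#' @param folder output directory (created if needed).
#' @param bits 8 or 16 bits per sample.
#' @return `folder`, invisibly.
#' @export
write_tiff_stack <- function(x, folder, bits = 8L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  arr <- if (inherits(x, "hole_mask")) 255 * x$voxels else x$intensities
  maxv <- 2^bits - 1
  arr <- pmin(pmax(round(arr), 0), maxv)   # integer grey levels; lossless for
                                           # integer-valued volumes
  nz <- dim(arr)[3]
  for (k in seq_len(nz)) {
    img <- t(arr[, , k]) / maxv   # writeTIFF expects [y, x] in [0, 1]
    tiff::writeTIFF(img, file.path(folder, sprintf("scan_%03d.tiff", k)),
                    bits.per.sample = bits, compression = "none")
  }
  sp <- x$spacing
  writeLines(c(sprintf("dx_um=%g", sp[1]), sprintf("dy_um=%g", sp[2]),
               sprintf("dz_um=%g", sp[3]), sprintf("source_id=%s", x$source_id)),
             file.path(folder, "metadata.txt"))
  invisible(folder)
}

#' Write or read a surface map as CSV
#'
#' Long format with 0-based grid indices: `x_index, z_index, y_um`.
#'
#' @param surface a [surface_map()].
#' @param file CSV path.
#' @return `write_surface_csv`: `file` invisibly; `read_surface_csv`:
#'   a [surface_map()].
#' @export
write_surface_csv <- function(surface, file) {
  m <- surface$y_um
  df <- data.frame(x_index = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
                   z_index = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
                   y_um = as.vector(m))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_surface_csv
#' @param kind surface kind for the object read back.
#' @export
read_surface_csv <- function(file, kind = c("RPE", "ILM")) {
  df <- read.csv(file)
  nx <- max(df$x_index) + 1L; nz <- max(df$z_index) + 1L
  m <- matrix(NA_real_, nx, nz)
  m[cbind(df$x_index + 1L, df$z_index + 1L)] <- df$y_um
  surface_map(m, match.arg(kind))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b logical arrays of identical dimensions, or [hole_mask()]s.
#' @return numeric in `[0, 1]` (`NaN` if both empty).
#' @export
dice <- function(a, b) {
  if (inherits(a, "hole_mask")) a <- a$voxels
  if (inherits(b, "hole_mask")) b <- b$voxels
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  2 * sum(a & b) / (sum(a) + sum(b))
}
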