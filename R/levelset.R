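#' Parameters of the LGDF level-set segmentation
#'
#' The segmentation evolves a signed field `phi` (negative inside) under a
#' local Gaussian distribution fitting (LGDF) energy: at every voxel the
#' interior and exterior intensities are modelled by Gaussians whose mean
#' and variance are estimated in a Gaussian window of physical scale
#' `sigma_um`, and the interface moves towards the region whose local
#' Gaussian log-likelihood of the voxel intensity is higher. A length
#' penalty (`mu`) and a distance-regularisation term (`nu`) are added.
#' All kernels and differential operators work in physical micrometre
#' units, so the strong Z anisotropy of OCT volumes is handled naturally.
#'
#' The time step is adaptive: a trial step that increases the discrete
#' energy is rejected and retried with half the step, so the energy is
#' non-increasing over accepted iterations by construction; `dt` is the
#' initial step in units of the finest voxel pitch.
#'
#' @param spacing a [voxel_spacing()] used for scale defaults.
#' @param sigma_um Gaussian window scale (default `3 * dx`).
#' @param lambda1,lambda2 interior / exterior data weights.
#' @param mu length-penalty (curvature) weight.
#' @param nu distance-regularisation weight.
#' @param dt initial time step.
#' @param max_iter iteration cap per scale.
#' @param tol convergence tolerance: relative change of segmented volume
#'   over `tol_window` accepted iterations.
#' @param tol_window window (iterations) for the convergence test.
#' @param scales multiscale downsampling factors, coarse to fine, applied
#'   in X and Y only (Z is already coarse); must end in 1.
#' @param eps_h_um Heaviside/delta smoothing width (default `1.5 * dy`).
#' @param min_var variance floor for the local Gaussians (intensities are
#'   normalised to `[0, 1]` before evolution, which also makes the
#'   segmentation invariant to affine intensity rescaling).
#' @param seed_quantile intensity quantile (within the ILM-RPE band) below
#'   which voxels seed the initial interior.
#' @param open_iters morphological opening radius (voxels) for the seed.
#' @param band_margin_vox margin (voxels along Y) kept above the ILM and
#'   below the RPE when cropping the working band.
#' @param restrict_margin_vox margin used when restricting the final mask
#'   to the inter-surface band.
#' @param max_frac divergence guard: failure if the interior exceeds this
#'   fraction of the working volume.
#' @return An object of class `level_set_params`.
#' @export
level_set_params <- function(spacing = voxel_spacing(5.47, 3.87, 30),
                             sigma_um = NULL, lambda1 = 1, lambda2 = 1,
                             mu = 0.2, nu = 0.2, dt = 0.1, max_iter = 500L,
                             tol = 1e-4, tol_window = 10L,
                             scales = c(4L, 2L, 1L), eps_h_um = NULL,
                             min_var = 1e-3, seed_quantile = 0.2,
                             open_iters = 1L, band_margin_vox = 6L,
                             restrict_margin_vox = 4L, max_frac = 0.9) {
  spacing <- as_spacing(spacing)
  if (is.null(sigma_um)) sigma_um <- 3 * spacing[1]
  if (is.null(eps_h_um)) eps_h_um <- 1.5 * spacing[2]
  if (sigma_um <= 0 || lambda1 <= 0 || lambda2 <= 0 || dt <= 0)
    stop("sigma_um, lambda1, lambda2 and dt must be positive")
  scales <- as.integer(scales)
  if (any(diff(scales) >= 0) && length(scales) > 1)
    stop("scales must be strictly decreasing")
  if (scales[length(scales)] != 1L) stop("scales must end at 1")
  structure(list(spacing = spacing, sigma_um = sigma_um,
                 lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu,
                 dt = dt, max_iter = as.integer(max_iter), tol = tol,
                 tol_window = as.integer(tol_window), scales = scales,
                 eps_h_um = eps_h_um, min_var = min_var,
                 seed_quantile = seed_quantile,
                 open_iters = as.integer(open_iters),
                 band_margin_vox = as.integer(band_margin_vox),
                 restrict_margin_vox = as.integer(restrict_margin_vox),
                 max_frac = max_frac),
            class = "level_set_params")
}

band_mask <- function(dims, dy, rpe_um, ilm_um) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  band <- array(FALSE, dim = dims)
  for (j in seq_len(ny)) {
    y <- (j - 1) * dy
    band[, j, ] <- y >= ilm_um & y < rpe_um
  }
  band
}

#' Initialise the level-set field from dark voxels between ILM and RPE
#'
#' The hole is hypo-reflective: the interior seed is the set of voxels in
#' the ILM-RPE band whose intensity lies below a configurable quantile of
#' the band intensities, cleaned by a morphological opening. `phi` is the
#' anisotropy-aware signed Euclidean distance to the seed boundary,
#' negative inside.
#'
#' @param volume an [oct_volume()].
#' @param rpe,ilm [surface_map()]s on the same grid.
#' @param params a [level_set_params()].
#' @return An object of class `level_set_field`: list with `phi` (3D
#'   array, um) and `spacing`.
#' @export
initialize_level_set <- function(volume, rpe, ilm,
                                 params = level_set_params(volume$spacing)) {
  stopifnot(inherits(volume, "oct_volume"))
  I <- volume$intensities
  dy <- volume$spacing[2]
  band <- array(FALSE, dim = dim(I))
  for (j in seq_len(dim(I)[2])) {
    y <- (j - 1) * dy
    band[, j, ] <- y >= ilm$y_um & y < rpe$y_um
  }
  if (!any(band)) stop("empty ILM-RPE band; surfaces look degenerate")
  thr <- quantile(I[band], params$seed_quantile, names = FALSE)
  seed <- band & I < thr
  if (params$open_iters > 0)
    seed <- morph3_cpp(seed, dim(I), params$open_iters, "open")
  if (!any(seed))
    stop(paste("empty level-set seed: no dark voxels below the",
               sprintf("%.0f%% band quantile;", 100 * params$seed_quantile),
               "raise seed_quantile or check that a hole is present"))
  phi <- signed_edt_cpp(seed, dim(I), volume$spacing)
  structure(list(phi = phi, spacing = volume$spacing),
            class = "level_set_field")
}

#' Evolve a level-set field under the LGDF energy
#'
#' Gradient descent on the local Gaussian distribution fitting energy with
#' adaptive, energy-monotone stepping (see [level_set_params()]).
#' Intensities are min-max normalised internally. Evolution stops at
#' convergence (relative segmented-volume change below `tol` over
#' `tol_window` iterations) or at the iteration cap; it fails with an
#' error if the interior collapses or overruns `max_frac` of the domain.
#'
#' @param volume an [oct_volume()].
#' @param field a [level_set_field()] from [initialize_level_set()].
#' @param params a [level_set_params()].
#' @param domain optional logical array: voxels allowed to evolve; `phi`
#'   is frozen (exterior) elsewhere. Used by [multiscale_segment()] to
#'   confine the vitreous leak to a chimney above the hole opening.
#' @return the evolved `level_set_field`, with an attribute `trace`: list
#'   with `energy` and `vol_frac` per accepted iteration, `iterations`,
#'   `converged`.
#' @export
evolve_lgdf <- function(volume, field, params = level_set_params(volume$spacing),
                        domain = NULL) {
  stopifnot(inherits(field, "level_set_field"))
  I <- volume$intensities
  rng <- range(I)
  In <- if (rng[2] > rng[1]) (I - rng[1]) / (rng[2] - rng[1]) else array(0, dim(I))
  phi <- field$phi
  if (is.null(domain)) {
    domain <- logical(0)
  } else {
    # the frozen exterior must start (and therefore stay) outside
    phi[!domain & phi <= 0] <- volume$spacing[2]
  }
  res <- lgdf_evolve_cpp(In, phi, dim(I), volume$spacing,
                         params$sigma_um, params$lambda1, params$lambda2,
                         params$mu, params$nu, params$dt, params$max_iter,
                         params$tol, params$tol_window, params$eps_h_um,
                         params$min_var, params$max_frac, domain)
  if (res$diverged_at > 0) {
    vf <- res$vol_frac[length(res$vol_frac)]
    stop(sprintf("level-set evolution diverged at iteration %d (interior %s)",
                 res$diverged_at,
                 if (vf <= 0) "vanished" else sprintf("reached %.0f%% of the domain", 100 * vf)))
  }
  out <- structure(list(phi = res$phi, spacing = volume$spacing),
                   class = "level_set_field")
  attr(out, "trace") <- list(energy = res$energy, vol_frac = res$vol_frac,
                             iterations = res$iterations,
                             converged = res$converged)
  out
}

downsample_map <- function(m, f) {
  if (f == 1L) return(m)
  mx <- nrow(m) %/% f
  out <- matrix(0, mx, ncol(m))
  for (i in seq_len(mx))
    out[i, ] <- colMeans(m[((i - 1) * f + 1):(i * f), , drop = FALSE])
  out
}

#' Multiscale 3D segmentation of the macular hole
#'
#' Runs the LGDF level set coarse-to-fine: the volume is cropped to the
#' ILM-RPE band (plus a margin), downsampled in X and Y by each factor in
#' `params$scales`, seeded at the coarsest scale from the dark-voxel
#' initialiser, and the converged interface at each scale seeds the next
#' finer one (signed-distance reinitialisation of the upsampled interior).
#' At the finest scale `phi <= 0` is thresholded to a mask restricted to
#' the inter-surface band plus `restrict_margin_vox`. The mask may still
#' protrude above the ILM opening where hole and vitreous are contiguous;
#' [curvature_surface_cut()] removes that.
#'
#' @param volume an [oct_volume()] (flattened frame recommended).
#' @param params a [level_set_params()].
#' @param rpe,ilm [surface_map()]s on the same grid.
#' @return a [hole_mask()] with attribute `scale_log` (iterations and
#'   convergence per scale).
#' @export
multiscale_segment <- function(volume, params, rpe, ilm) {
  stopifnot(inherits(volume, "oct_volume"))
  I <- volume$intensities
  d <- dim(I); dy <- volume$spacing[2]
  j0 <- max(1L, floor(min(ilm$y_um) / dy) + 1L - params$band_margin_vox)
  j1 <- min(d[2], ceiling(max(rpe$y_um) / dy) + 1L + params$band_margin_vox)
  off_um <- (j0 - 1L) * dy
  Ic <- I[, j0:j1, , drop = FALSE]
  rpe_c <- surface_map(rpe$y_um - off_um, "RPE")
  ilm_c <- surface_map(pmax(ilm$y_um - off_um, 0), "ILM")
  vol_c <- oct_volume(Ic, volume$spacing, volume$source_id)

  field <- NULL
  logs <- list()
  for (s in seq_along(params$scales)) {
    f <- params$scales[s]
    sp_f <- voxel_spacing(volume$spacing[1] * f, volume$spacing[2] * f,
                          volume$spacing[3])
    If <- if (f == 1L) Ic else downsample_xy_cpp(Ic, dim(Ic), f)
    vol_f <- oct_volume(If, sp_f, volume$source_id)
    rpe_f <- surface_map(downsample_map(rpe_c$y_um, f), "RPE")
    ilm_f <- surface_map(downsample_map(ilm_c$y_um, f), "ILM")
    par_f <- params; par_f$spacing <- sp_f
    if (is.null(field)) {
      field <- initialize_level_set(vol_f, rpe_f, ilm_f, par_f)
    } else {
      mask_prev <- field$phi <= 0
      up <- upsample_mask_xy(mask_prev, dim(If))
      phi <- signed_edt_cpp(up, dim(If), sp_f)
      field <- structure(list(phi = phi, spacing = sp_f),
                         class = "level_set_field")
    }
    # evolution domain: the full inter-surface band, plus -- only above
    # the footprint of the current interior (dilated) -- a margin above
    # the ILM. The hole communicates with the vitreous solely through its
    # opening; an unrestricted domain lets the interface flood the
    # vitreous sideways for hundreds of iterations before converging.
    foot <- dilate2(apply(field$phi <= 0, c(1, 3), any), 3L)
    domain <- array(FALSE, dim = dim(If))
    for (j in seq_len(dim(If)[2])) {
      y <- (j - 1) * sp_f[2]
      in_band <- y >= ilm_f$y_um & y < rpe_f$y_um + dy
      chimney <- foot & y >= ilm_f$y_um - params$restrict_margin_vox * dy &
        y < ilm_f$y_um
      domain[, j, ] <- in_band | chimney
    }
    field <- tryCatch(evolve_lgdf(vol_f, field, par_f, domain = domain),
                      error = function(e)
                        stop("segmentation failed at scale ", f, ": ",
                             conditionMessage(e)))
    # clip the interior to the band between the surfaces (plus margin)
    # before handing it to the next scale: a homogeneous slab mislabelled
    # at a coarse scale is locally self-consistent under the LGDF
    # statistics and would otherwise survive refinement
    # the inherited interior stops one voxel short of the base plane: the
    # next scale re-finds the base rows from the data, instead of
    # inheriting coarse-scale voxels that its local statistics would
    # freeze in place
    clip <- band_keep(dim(If), sp_f[2], ilm_f$y_um, rpe_f$y_um,
                      params$restrict_margin_vox * dy, -dy)
    trc <- attr(field, "trace")
    field$phi[!clip & field$phi <= 0] <- sp_f[2]
    attr(field, "trace") <- trc
    tr <- attr(field, "trace")
    logs[[length(logs) + 1L]] <- list(scale = f, iterations = tr$iterations,
                                      converged = tr$converged,
                                      energy = tr$energy,
                                      vol_frac = tr$vol_frac)
  }
  mask_c <- field$phi <= 0
  keep <- band_keep(dim(Ic), dy, ilm_c$y_um, rpe_c$y_um,
                    params$restrict_margin_vox * dy, dy)
  mask_c <- mask_c & keep
  full <- array(FALSE, dim = d)
  full[, j0:j1, ] <- mask_c
  out <- hole_mask(full, volume$spacing, volume$source_id)
  attr(out, "scale_log") <- logs
  out
}

# logical array: voxels within [ilm - above, rpe + below), physical units.
# The supra-ILM margin is generous (vitreous leak through the opening is
# expected and later cut); the sub-RPE margin is one voxel -- the hole
# never extends below the base plane, and a wider margin lets the bright
# RPE band lock in as a self-consistent interior slab at coarse scales.
band_keep <- function(dims, dy_scale, ilm_um, rpe_um, above_um, below_um) {
  keep <- array(FALSE, dim = dims)
  for (j in seq_len(dims[2])) {
    y <- (j - 1) * dy_scale
    keep[, j, ] <- y >= ilm_um - above_um & y < rpe_um + below_um
  }
  keep
}

# nearest-neighbour upsampling of a coarse X/Y mask onto target dims
upsample_mask_xy <- function(mask, target_dim) {
  dc <- dim(mask)
  f <- target_dim[1] %/% dc[1]
  ix <- pmin(ceiling(seq_len(target_dim[1]) / f), dc[1])
  iy <- pmin(ceiling(seq_len(target_dim[2]) / f), dc[2])
  mask[ix, iy, , drop = FALSE]
}
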