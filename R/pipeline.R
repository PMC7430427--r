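#' Run the full segmentation and morphometry pipeline on a TIFF folder
#'
#' Executes read -> surface estimation -> flattening -> multiscale LGDF
#' segmentation -> curvature surface cut -> morphometry, writing the
#' report (CSV + JSON), section profiles (CSV), the mask (TIFF stack),
#' the surfaces (CSV) and a run manifest (JSON) into `out_dir`. Any stage
#' failure aborts with the stage name; the manifest records per-stage
#' status and is written on success and on failure alike.
#'
#' @param folder TIFF folder readable by [read_tiff_stack()].
#' @param config named list overriding [level_set_params()] /
#'   [cut_params()] arguments and `spacing` (`c(dx, dy, dz)` in um).
#' @param out_dir output directory; `NULL` to skip writing.
#' @return invisibly, a list with `fit` (the [macular_hole()] object),
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(folder, config = list(), out_dir = NULL) {
  manifest <- list(subcommand = "run", inputs = normalizePath(folder,
                                                              mustWork = FALSE),
                   config = config,
                   tool_version = as.character(utils::packageVersion("holemorph")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  config_hash <- substr(digest_config(config), 1, 12)
  manifest$config_hash <- config_hash
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(status = if (ok) "ok" else "failed",
                                     message = if (ok) "" else conditionMessage(res))
    if (!ok) {
      manifest$ended <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      if (!is.null(out_dir)) write_manifest(manifest, out_dir)
      stop("pipeline aborted at stage '", name, "': ",
           conditionMessage(res), call. = FALSE)
    }
    res
  }
  spacing <- if (!is.null(config$spacing)) as_spacing(config$spacing) else NULL
  volume <- stage("read", read_tiff_stack(folder, spacing))
  surfaces <- stage("surfaces", estimate_surfaces(volume))
  params <- do.call(level_set_params,
                    c(list(spacing = volume$spacing),
                      config[intersect(names(config),
                                       names(formals(level_set_params))[-1])]))
  cutp <- do.call(cut_params,
                  config[intersect(names(config), names(formals(cut_params)))])
  fit <- stage("segment",
               macular_hole(volume, params = params, cut = cutp,
                            surfaces = surfaces))
  report <- fit$report
  manifest$ended <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- as.data.frame(report)
    df$config_hash <- config_hash
    write.csv(df, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(c(report[setdiff(names(report), "sections")],
                           list(config_hash = config_hash)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(report$sections, file.path(out_dir, "sections.csv"),
              row.names = FALSE)
    write_tiff_stack(fit$mask, file.path(out_dir, "mask"))
    write_surface_csv(fit$surfaces$rpe, file.path(out_dir, "surface_rpe.csv"))
    write_surface_csv(fit$surfaces$ilm, file.path(out_dir, "surface_ilm.csv"))
    write_manifest(manifest, out_dir)
  }
  invisible(list(fit = fit, report = report, manifest = manifest))
}

write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

digest_config <- function(config) {
  # order-independent text fingerprint of the config (no extra deps)
  if (length(config) == 0) return("00000000000000")
  txt <- paste(sort(vapply(names(config), function(n)
    paste0(n, "=", paste(format(config[[n]], digits = 15), collapse = ",")),
    character(1))), collapse = ";")
  raw <- utils::head(charToRaw(txt), 10000)
  sprintf("%08x%06x", sum(as.integer(raw) * seq_along(raw)) %% 0xFFFFFFF,
          length(raw))
}

#' Generate a seeded corpus of phantoms for recovery testing
#'
#' Writes `n` phantoms derived from a template spec with jittered hole
#' parameters (semi-axes, meridians, waist height, tilt), each as a TIFF
#' stack plus truth-mask stack, and a `truth.csv` collecting the analytic
#' ground truth of every phantom.
#'
#' @param spec template [phantom_spec()].
#' @param n number of phantoms.
#' @param seed integer seed controlling both the jitter and the speckle.
#' @param dir output directory; `NULL` to skip writing (specs and truths
#'   are still returned).
#' @param jitter relative jitter amplitude applied to the semi-axes and
#'   tilt (uniform in `1 +/- jitter`); meridians are drawn uniformly in
#'   `[0, 180)`.
#' @param meridian_mode `"independent"` draws base, waist and top
#'   meridians separately (the meridian then rotates along height);
#'   `"rigid"` applies one common random rotation to all three, which is
#'   the regime in which a section meridian is well-defined at every
#'   height.
#' @return invisibly, list of per-phantom lists with `spec`, `truth
#'   parameters`, and (when written) `folder`.
#' @export
run_phantom_suite <- function(spec = phantom_spec(), n = 10L, seed = 1L,
                              dir = NULL, jitter = 0.15,
                              meridian_mode = c("independent", "rigid")) {
  meridian_mode <- match.arg(meridian_mode)
  draws <- with_seed(seed, matrix(runif(n * 15), n, 15))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    u <- draws[i, ]
    # a common size factor per cross-section plus a small per-axis jitter:
    # jittering the axes independently would wash out the eccentricity
    # that makes meridians identifiable
    jit <- function(v, us, uc) v * (1 - jitter + 2 * jitter * uc) *
      (1 - jitter / 4 + jitter / 2 * us)
    sp_i <- spec
    sp_i$base[1:2] <- jit(spec$base[1:2], u[1:2], u[13])
    sp_i$waist[1:2] <- jit(spec$waist[1:2], u[3:4], u[14])
    sp_i$top[1:2] <- jit(spec$top[1:2], u[5:6], u[15])
    if (meridian_mode == "rigid") {
      rot <- 180 * u[7]
      sp_i$base[3] <- (spec$base[3] + rot) %% 180
      sp_i$waist[3] <- (spec$waist[3] + rot) %% 180
      sp_i$top[3] <- (spec$top[3] + rot) %% 180
    } else {
      sp_i$base[3] <- 180 * u[7]
      sp_i$waist[3] <- 180 * u[8]
      sp_i$top[3] <- 180 * u[9]
    }
    sp_i$waist_frac <- 0.35 + 0.3 * u[10]
    sp_i$tilt_um <- spec$tilt_um * (2 * u[11:12] - 1)
    sp_i$seed <- spec$seed + i
    validate_phantom_spec(sp_i)
    ph <- generate_phantom(sp_i)
    rec <- list(spec = sp_i, truth = ph$truth_params)
    if (!is.null(dir)) {
      folder <- file.path(dir, sprintf("phantom_%02d", i))
      write_tiff_stack(ph$volume, file.path(folder, "volume"))
      write_tiff_stack(ph$truth, file.path(folder, "truth_mask"))
      rec$folder <- folder
    }
    out[[i]] <- rec
  }
  if (!is.null(dir)) {
    tr <- do.call(rbind, lapply(seq_len(n), function(i) {
      t <- out[[i]]$truth
      data.frame(id = i, as.data.frame(t[setdiff(names(t), "ivts_class")]),
                 ivts_class = t$ivts_class)
    }))
    write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(out)
}
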