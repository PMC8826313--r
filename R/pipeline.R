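# End-to-end orchestration: simulate -> absorbance -> trial phase maps ->
# QC -> averaging -> delay correction -> degree maps -> VFS ->
# segmentation -> (optional) reliability, with a reproducible manifest.

#' Simulate a full imaging session
#'
#' Generates `params$n_blocks` blocks per direction with
#' [simulate_movie()] and reduces each to single-trial phase maps with
#' [process_block()] (movies are discarded block by block, so memory
#' stays bounded). Block seeds are derived deterministically from
#' `seed`.
#'
#' @param gt a [make_ground_truth()] object.
#' @param params a [sim_params()].
#' @param cfg a [stim_config()].
#' @param directions which sweep directions to acquire.
#' @param seed session seed (default `params$seed`).
#' @return a list of class `sim_session`: `maps` (per-direction lists of
#'   single-trial [phase_map()]s), `bad` (per-direction logical vectors,
#'   the planted bad-trial labels), plus `gt`, `params`, `cfg`.
#' @export
simulate_session <- function(gt, params, cfg = stim_config(),
                             directions = c("NT", "TN", "IS", "SI"),
                             seed = params$seed) {
  maps <- bad <- stats::setNames(vector("list", length(directions)), directions)
  for (d in directions) {
    maps[[d]] <- list(); bad[[d]] <- logical(0)
    for (b in seq_len(params$n_blocks)) {
      sim <- simulate_movie(gt, params, cfg, direction = d,
                            seed = child_seed(seed, paste(d, b)), block_id = b)
      maps[[d]] <- c(maps[[d]], process_block(sim$stack, sim$trials, cfg,
                                              baseline_window = c(0, params$baseline_s)))
      bad[[d]] <- c(bad[[d]], sim$bad_sweeps)
    }
  }
  structure(list(maps = maps, bad = bad, gt = gt, params = params, cfg = cfg),
            class = "sim_session")
}

#' Quality-control a session and pair opposing sweeps
#'
#' Runs [trial_quality()] per direction and pairs the surviving forward
#' and backward sweep-trials of each axis in acquisition order
#' (truncating to the shorter side), yielding the pair-trials that the
#' delay correction and the reliability analysis consume.
#'
#' @param session a [simulate_session()] result (or any list with the
#'   same `maps` field).
#' @param threshold QC threshold; `NULL` skips QC.
#' @return a list: `pairs_az`, `pairs_el` (lists of
#'   `list(fwd =, bwd =)`), and `qc` (per-direction QC reports).
#' @export
qc_and_pair <- function(session, threshold = 0.6) {
  kept <- list(); qc <- list()
  for (d in names(session$maps)) {
    if (is.null(threshold)) {
      kept[[d]] <- session$maps[[d]]
    } else {
      q <- trial_quality(session$maps[[d]], threshold = threshold)
      kept[[d]] <- q$kept; qc[[d]] <- q$report
    }
  }
  pair_up <- function(f, b) {
    n <- min(length(f), length(b))
    lapply(seq_len(n), function(i) list(fwd = f[[i]], bwd = b[[i]]))
  }
  list(pairs_az = if (all(c("NT", "TN") %in% names(kept)))
         pair_up(kept$NT, kept$TN) else list(),
       pairs_el = if (all(c("IS", "SI") %in% names(kept)))
         pair_up(kept$IS, kept$SI) else list(),
       qc = qc)
}

#' Build one axis map from pair-trials
#'
#' @param pairs list of `list(fwd =, bwd =)` pair-trials.
#' @param cfg a [stim_config()].
#' @param amplitude_floor passed to [phase_to_visual_degrees()].
#' @param presmooth_sigma Gaussian SD (pixels) for complex-field smoothing
#'   of the averaged forward/backward maps before delay correction
#'   (amplitude-weighted phase denoising); 0 disables it.
#' @return a [retinotopic_map()].
#' @export
build_axis_map <- function(pairs, cfg = stim_config(), amplitude_floor = 0.05,
                           presmooth_sigma = 2) {
  if (!length(pairs)) isi_stop("isimap_phase_error", "no pair-trials supplied")
  fwd <- smooth_map(average_phase_maps(lapply(pairs, `[[`, "fwd")), presmooth_sigma)
  bwd <- smooth_map(average_phase_maps(lapply(pairs, `[[`, "bwd")), presmooth_sigma)
  phase_to_visual_degrees(absolute_phase(fwd, bwd), cfg,
                          amplitude_floor = amplitude_floor)
}

# save a retinotopic/vfs map as float TIFF + JSON metadata
save_map <- function(map, path) {
  v <- if (inherits(map, "vfs_map")) map$s else map$values
  meta <- unclass(map); meta$values <- NULL; meta$s <- NULL
  meta$class <- class(map)
  finite <- is.finite(v)
  lo <- if (any(finite)) min(v[finite]) else 0
  hi <- if (any(finite)) max(v[finite]) else 1
  scale <- if (hi > lo) hi - lo else 1
  enc <- v; enc[!finite] <- lo
  tiff::writeTIFF(list((enc - lo) / scale, finite * 1), path, bits.per.sample = 32L)
  meta$encoding <- list(offset = lo, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# read back a map written by save_map
load_map <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- pages[[1]] * meta$encoding$scale + meta$encoding$offset
  v[pages[[2]] < 0.5] <- NaN
  if ("vfs_map" %in% meta$class)
    structure(list(s = v, sigma = meta$sigma, pixel_scale = meta$pixel_scale,
                   n_trials = meta$n_trials), class = "vfs_map")
  else
    retinotopic_map(v, axis = meta$axis, span = meta$span,
                    pixel_scale = meta$pixel_scale, n_trials = meta$n_trials)
}

#' Run the processing pipeline end to end
#'
#' Stages: `simulate` (synthetic session with ground truth), `process`
#' (QC, averaging, delay correction, degree maps), `fieldsign` (VFS +
#' segmentation), `reliability` (centroid error curve over a trial-count
#' grid). All randomness flows from `seed`; a JSON manifest recording
#' parameters, seeds and output files is written to `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed root seed.
#' @param stages character vector of stages to run.
#' @param cfg a [stim_config()].
#' @param params a [sim_params()].
#' @param layout ground-truth layout preset or [area_spec()] list.
#' @param n_grid trial counts for the reliability stage.
#' @param n_reps resamples per trial count.
#' @param seg_threshold,seg_min_size segmentation parameters.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         stages = c("simulate", "process", "fieldsign"),
                         cfg = stim_config(), params = sim_params(seed = seed),
                         layout = "six_area",
                         n_grid = c(5, 10, 20, 30, 43, 50, 60, 75, 90),
                         n_reps = 20, seg_threshold = 0.3, seg_min_size = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = stages,
                   config = unclass(cfg), params = unclass(params),
                   version = as.character(utils::packageVersion("isimap")),
                   outputs = list())
  log_stage <- function(stage, ...) {
    message(jsonlite::toJSON(c(list(stage = stage), list(...)), auto_unbox = TRUE))
  }
  add_out <- function(key, path) manifest$outputs[[key]] <<- path

  if ("simulate" %in% stages) {
    log_stage("simulate", layout = if (is.character(layout)) layout else "custom")
    gt <- make_ground_truth(layout, image_size = params$image_size, cfg = cfg,
                            pixel_scale = params$pixel_scale)
    session <- simulate_session(gt, params, cfg, seed = seed)
    vasc <- simulate_vasculature(params$image_size, seed = child_seed(seed, "vasc"))
    write_image(vasc, file.path(out_dir, "vasculature.tif"))
    add_out("vasculature", "vasculature.tif")
    gt_manifest <- list(area_names = gt$area_names,
                        signs = vapply(gt$areas, `[[`, 0L, "sign"),
                        hemodynamic_delay = gt$hemodynamic_delay,
                        bad_trials = session$bad)
    jsonlite::write_json(gt_manifest, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    add_out("ground_truth", "ground_truth.json")
  } else isi_stop("isimap_config_error",
                  "processing experimental recordings requires the simulate stage in this build")

  paired <- NULL
  if ("process" %in% stages) {
    log_stage("process", qc_threshold = cfg$qc_threshold)
    paired <- qc_and_pair(session, threshold = cfg$qc_threshold)
    for (d in names(paired$qc))
      utils::write.csv(paired$qc[[d]],
                       file.path(out_dir, sprintf("qc_%s.csv", d)), row.names = FALSE)
    az <- build_axis_map(paired$pairs_az, cfg)
    el <- build_axis_map(paired$pairs_el, cfg)
    save_map(az, file.path(out_dir, "azimuth.tif")); add_out("azimuth", "azimuth.tif")
    save_map(el, file.path(out_dir, "elevation.tif")); add_out("elevation", "elevation.tif")
  }

  if ("fieldsign" %in% stages) {
    if (is.null(paired)) isi_stop("isimap_config_error", "fieldsign requires process")
    log_stage("fieldsign", sigma = cfg$smooth_sigma)
    vfs <- visual_field_sign(az, el, sigma = cfg$smooth_sigma)
    save_map(vfs, file.path(out_dir, "vfs.tif")); add_out("vfs", "vfs.tif")
    areas <- segment_areas(vfs, threshold = seg_threshold, min_size = seg_min_size)
    area_json <- lapply(areas, function(a)
      list(name = a$name, sign = a$sign, area_px = a$area_px,
           centroid_px = unname(a$centroid_px), centroid_um = unname(a$centroid_um)))
    jsonlite::write_json(area_json, file.path(out_dir, "areas.json"),
                         auto_unbox = TRUE, digits = NA)
    add_out("areas", "areas.json")
  }

  if ("reliability" %in% stages) {
    if (is.null(paired)) isi_stop("isimap_config_error", "reliability requires process")
    grid <- sort(unique(pmin(n_grid, length(paired$pairs_az))))
    log_stage("reliability", n_grid = grid, n_reps = n_reps)
    subs <- stats::setNames(lapply(grid, function(n)
      subsample_average(paired$pairs_az, n = n, n_reps = n_reps,
                        seed = child_seed(seed, paste("rel", n)), cfg = cfg)),
      grid)
    reference <- build_axis_map(paired$pairs_az, cfg)
    curve <- centroid_error_curve(subs, reference)
    utils::write.csv(as.data.frame(curve), file.path(out_dir, "error_curve.csv"),
                     row.names = FALSE)
    add_out("error_curve", "error_curve.csv")
    manifest$n_star_100um <- as.integer(min_trials_for_criterion(curve, 100))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Plot a retinotopic or field-sign map
#'
#' @param x a `retinotopic_map` or `vfs_map`.
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @export
plot.retinotopic_map <- function(x, main = sprintf("%s (deg)", x$axis), ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1], main = main, axes = FALSE,
                  col = grDevices::hcl.colors(64, "Spectral"), ...)
}

#' @rdname plot.retinotopic_map
#' @export
plot.vfs_map <- function(x, main = "visual field sign", ...) {
  graphics::image(t(x$s)[, nrow(x$s):1], main = main, axes = FALSE, zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red"), ...)
}

#' Save an overlay figure: vasculature, area outlines, craniotomies
#'
#' @param vasculature background image matrix.
#' @param areas [segment_areas()] result.
#' @param craniotomies optional list of [craniotomy()] objects (drawn as
#'   circles, assuming map-frame coordinates).
#' @param path output PNG path.
#' @param pixel_scale micrometers per pixel (for craniotomy radii).
#' @return `path`, invisibly.
#' @export
save_overlay_png <- function(vasculature, areas, craniotomies = NULL, path,
                             pixel_scale = 6) {
  grDevices::png(path, width = 720, height = 720)
  on.exit(grDevices::dev.off())
  H <- nrow(vasculature); W <- ncol(vasculature)
  graphics::image(x = 0:(W - 1), y = 0:(H - 1),
                  z = t(vasculature)[, H:1, drop = FALSE],
                  col = grDevices::gray.colors(128), axes = FALSE,
                  xlab = "", ylab = "", main = "areas over vasculature")
  for (a in areas) {
    idx <- which(a$mask, arr.ind = TRUE)
    graphics::points(idx[, 2] - 1, H - idx[, 1],
                     pch = ".", col = if (a$sign > 0) "red" else "blue")
    graphics::text(a$centroid_px["col"], H - 1 - a$centroid_px["row"], a$name,
                   col = "white", cex = 1.4)
  }
  for (cr in craniotomies %||% list()) {
    t_ <- seq(0, 2 * pi, length.out = 100)
    r <- cr$radius_um / pixel_scale
    graphics::lines(cr$center[2] + r * cos(t_), H - 1 - cr$center[1] + r * sin(t_),
                    col = "yellow", lwd = 2)
  }
  invisible(path)
}
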