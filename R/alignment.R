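# Landmark-based rigid alignment and craniotomy targeting.

#' Estimate a rigid X-Y translation from fiduciary point pairs
#'
#' The least-squares translation between two point sets matched pair by
#' pair is the mean displacement vector. Rotation and scaling are
#' deliberately refused: mismatched magnifications should be fixed at
#' acquisition, not silently warped away.
#'
#' @param fids data frame with columns `xa, ya, xb, yb` (pixel
#'   coordinates of the same landmarks in image A and image B), at least
#'   one pair.
#' @return a list: `shift = c(dy, dx)` mapping A coordinates into B
#'   (`yb ~ ya + dy`), per-pair `residuals`, and `rms` residual. An RMS
#'   above 20 px triggers a landmark-quality warning.
#' @export
rigid_align_points <- function(fids) {
  need <- c("xa", "ya", "xb", "yb")
  if (!all(need %in% names(fids)) || nrow(fids) < 1)
    isi_stop("isimap_align_error", "need >= 1 pair with columns xa, ya, xb, yb")
  dy <- mean(fids$yb - fids$ya)
  dx <- mean(fids$xb - fids$xa)
  res <- sqrt((fids$yb - fids$ya - dy)^2 + (fids$xb - fids$xa - dx)^2)
  rms <- sqrt(mean(res^2))
  if (rms > 20)
    isi_warn("fiduciary residual RMS %.1f px exceeds 20 px: check landmark quality", rms)
  list(shift = c(dy = dy, dx = dx), residuals = res, rms = rms)
}

#' Specify a craniotomy
#'
#' @param center `(row, col)` center in the craniotomy-image frame,
#'   pixels (0-based).
#' @param radius_um radius in micrometers (craniotomies for silicon
#'   probes run ~100-500 um across).
#' @param expected_area optional area-name expectation, recorded only.
#' @return a list of class `craniotomy`.
#' @export
craniotomy <- function(center, radius_um = 250, expected_area = NULL) {
  if (radius_um <= 0) isi_stop("isimap_align_error", "radius must be positive")
  structure(list(center = as.numeric(center), radius_um = radius_um,
                 expected_area = expected_area),
            class = "craniotomy")
}

#' Expected retinotopic coordinates at a craniotomy
#'
#' Shifts the craniotomy disk into the map frame and averages the finite
#' map values whose pixel centers fall inside the disk
#' (pixel-center-in-circle membership, resolution independent).
#'
#' @param cran a [craniotomy()].
#' @param shift `c(dy, dx)` translation from the craniotomy-image frame
#'   into the map frame (e.g. from [rigid_align_points()]).
#' @param azimuth,elevation [retinotopic_map()]s; `elevation` optional.
#' @param areas optional [segment_areas()] result used to report which
#'   area contains the shifted center.
#' @return a list: `azimuth_deg`, `elevation_deg` (NA if no elevation
#'   map), `n_px` pixels averaged, `center_map` the shifted center, and
#'   `area` (name or NA).
#' @export
craniotomy_expected_retinotopy <- function(cran, shift = c(0, 0), azimuth,
                                           elevation = NULL, areas = NULL) {
  ctr <- cran$center + c(shift[1], shift[2])
  r_px <- cran$radius_um / azimuth$pixel_scale
  H <- nrow(azimuth$values); W <- ncol(azimuth$values)
  rows <- matrix(0:(H - 1), H, W); cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  disk <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r_px^2
  vals <- azimuth$values[disk]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    isi_stop("isimap_coverage_error",
             "craniotomy disk at (%.1f, %.1f) contains no finite map pixels",
             ctr[1], ctr[2])
  el <- NA_real_
  if (!is.null(elevation)) {
    ev <- elevation$values[disk]
    el <- mean(ev[is.finite(ev)])
  }
  area_name <- NA_character_
  if (!is.null(areas)) {
    rr <- round(ctr[1]) + 1; cc <- round(ctr[2]) + 1
    for (a in areas)
      if (rr >= 1 && cc >= 1 && rr <= H && cc <= W && a$mask[rr, cc]) {
        area_name <- a$name; break
      }
  }
  list(azimuth_deg = mean(vals), elevation_deg = el, n_px = length(vals),
       center_map = ctr, area = area_name)
}
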