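# Reliability analysis: how map quality depends on the number of trials.
#
# The sampling unit here is the pair-trial (one forward + one backward
# sweep of the same axis), since a delay-corrected map needs both
# directions.

#' Build trial-limited maps by resampling pair-trials
#'
#' Draws `n` pair-trials uniformly (with or without replacement), runs
#' the averaging -> delay-correction -> degree-conversion pipeline on
#' each draw, and (when elevation pairs are supplied too) computes the
#' VFS map of each resample. Deterministic for a given seed.
#'
#' @param pairs list of pair-trials for the primary axis; each element is
#'   `list(fwd = <phase_map>, bwd = <phase_map>)`.
#' @param n number of pair-trials per resample.
#' @param n_reps number of resamples.
#' @param with_replacement logical.
#' @param seed integer seed.
#' @param cfg a [stim_config()].
#' @param pairs_el optional list of elevation pair-trials (resampled with
#'   their own indices when of different length).
#' @param sigma smoothing width for the VFS computation.
#' @param amplitude_floor passed to [phase_to_visual_degrees()].
#' @param presmooth_sigma complex-field smoothing width before delay
#'   correction, as in [build_axis_map()].
#' @return a list of length `n_reps`; each element has `map` (the
#'   primary-axis [retinotopic_map()]), `indices`, and when elevation
#'   pairs were given, `map_el` and `vfs`.
#' @export
subsample_average <- function(pairs, n, n_reps = 20, with_replacement = FALSE,
                              seed = 1, cfg = stim_config(), pairs_el = NULL,
                              sigma = cfg$smooth_sigma, amplitude_floor = 0.05,
                              presmooth_sigma = 2) {
  if (!with_replacement && n > length(pairs))
    isi_stop("isimap_resample_error",
             "cannot draw %d of %d pair-trials without replacement", n, length(pairs))
  if (n_reps < 1) isi_stop("isimap_resample_error", "n_reps must be >= 1")
  build_map <- function(pp, idx, floor) {
    fwd <- smooth_map(average_phase_maps(lapply(pp[idx], `[[`, "fwd")), presmooth_sigma)
    bwd <- smooth_map(average_phase_maps(lapply(pp[idx], `[[`, "bwd")), presmooth_sigma)
    am <- absolute_phase(fwd, bwd)
    phase_to_visual_degrees(am, cfg, amplitude_floor = floor)
  }
  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample(length(pairs), n, replace = with_replacement)
      out <- list(map = build_map(pairs, idx, amplitude_floor), indices = idx)
      if (!is.null(pairs_el)) {
        idx_el <- if (length(pairs_el) == length(pairs)) idx
                  else sample(length(pairs_el), min(n, length(pairs_el)),
                              replace = with_replacement)
        out$map_el <- build_map(pairs_el, idx_el, amplitude_floor)
        out$vfs <- visual_field_sign(out$map, out$map_el, sigma = sigma)
      }
      out
    })
  })
}

#' Centroid error versus a reference map
#'
#' For each trial count, matches the 10-degree contour bins of every
#' resampled map with those of the reference map and averages the
#' per-bin centroid Euclidean distances (micrometers). Optionally
#' compares the distributions of subsampled versus reference centroid
#' coordinates by the Mann-Whitney U test, Bonferroni-corrected across
#' the trial-count grid.
#'
#' @param subsamples named list: one entry per trial count `n`, each a
#'   list of resamples as returned by [subsample_average()].
#' @param reference the reference [retinotopic_map()].
#' @param bin contour bin width, degrees.
#' @param mask optional logical matrix (e.g. the reference V1 mask)
#'   restricting the centroid analysis.
#' @param test run the rank-sum comparison.
#' @return a `data.frame` (class `error_curve`): `n, mean_um, sd_um,
#'   n_reps, n_bins`, plus `p_value` (Bonferroni-adjusted) when
#'   `test = TRUE`.
#' @export
centroid_error_curve <- function(subsamples, reference, bin = 10, mask = NULL,
                                 test = FALSE) {
  ref_cc <- contours_and_centroids(reference, bin = bin, mask = mask)
  scale <- reference$pixel_scale
  ns <- as.integer(names(subsamples))
  rows <- lapply(seq_along(subsamples), function(k) {
    reps <- subsamples[[k]]
    per_rep <- vapply(reps, function(r) {
      cc <- contours_and_centroids(r$map, bin = bin, mask = mask)
      shared <- intersect(cc$bin_deg, ref_cc$bin_deg)
      if (!length(shared)) return(NA_real_)
      a <- cc[match(shared, cc$bin_deg), ]
      b <- ref_cc[match(shared, ref_cc$bin_deg), ]
      mean(sqrt((a$row - b$row)^2 + (a$col - b$col)^2)) * scale
    }, numeric(1))
    if (all(is.na(per_rep)))
      isi_stop("isimap_resample_error",
               "no contour bins shared with the reference at n = %d", ns[k])
    data.frame(n = ns[k], mean_um = mean(per_rep, na.rm = TRUE),
               sd_um = stats::sd(per_rep, na.rm = TRUE),
               n_reps = sum(!is.na(per_rep)),
               n_bins = nrow(ref_cc))
  })
  curve <- do.call(rbind, rows)
  if (test) {
    pvals <- vapply(seq_along(subsamples), function(k) {
      sub_coords <- unlist(lapply(subsamples[[k]], function(r) {
        cc <- contours_and_centroids(r$map, bin = bin, mask = mask)
        c(cc$row, cc$col)
      }))
      ref_coords <- c(ref_cc$row, ref_cc$col)
      if (length(sub_coords) < 2) return(NA_real_)
      suppressWarnings(stats::wilcox.test(sub_coords, ref_coords)$p.value)
    }, numeric(1))
    curve$p_value <- pmin(pvals * length(pvals), 1)
  }
  structure(curve, class = c("error_curve", "data.frame"))
}

#' Smallest trial count meeting an error criterion
#'
#' Returns the smallest sampled `n` whose mean error is below the
#' criterion *and stays below it at every larger sampled n* (a sustained
#' crossing, so a single lucky draw cannot pass).
#'
#' @param curve an [centroid_error_curve()] result.
#' @param criterion error criterion in micrometers; the 100 um default
#'   is the typical craniotomy size, i.e. the targeting precision that
#'   matters downstream.
#' @return the trial count, or `NA` (flagged `"not reached"`) if no
#'   sustained crossing exists.
#' @export
min_trials_for_criterion <- function(curve, criterion = 100) {
  if (nrow(curve) < 2)
    isi_stop("isimap_resample_error", "need at least two trial counts")
  ord <- order(curve$n)
  below <- curve$mean_um[ord] < criterion
  sustained <- rev(cumprod(rev(below))) == 1
  if (!any(sustained)) {
    out <- NA_integer_
    attr(out, "status") <- "not reached"
    return(out)
  }
  n_star <- curve$n[ord][which(sustained)[1]]
  attr(n_star, "status") <- "reached"
  n_star
}

#' Rank-based AUROC
#'
#' Area under the ROC curve for separating `signal` from `noise` values,
#' computed from the Mann-Whitney U statistic (ties counted half).
#'
#' @param signal,noise numeric vectors.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(signal, noise) {
  signal <- signal[is.finite(signal)]; noise <- noise[is.finite(noise)]
  r <- rank(c(signal, noise))
  (sum(r[seq_along(signal)]) - length(signal) * (length(signal) + 1) / 2) /
    (length(signal) * length(noise))
}

# classification boundary maximizing balanced accuracy on reference data
best_boundary <- function(signal, noise) {
  signal <- signal[is.finite(signal)]; noise <- noise[is.finite(noise)]
  if (!length(signal) || !length(noise))
    isi_stop("isimap_roc_error", "no finite VFS values inside an ROI")
  vals <- sort(unique(c(signal, noise)))
  cand <- c(vals[1] - 1, (vals[-1] + vals[-length(vals)]) / 2, vals[length(vals)] + 1)
  bacc <- vapply(cand, function(b)
    (mean(signal > b) + mean(noise <= b)) / 2, numeric(1))
  cand[which.max(bacc)]
}

#' ROC detectability of areas versus trial count
#'
#' For each area, the "signal" distribution is the sign-rectified VFS
#' value (`S` times the area's reference sign) inside the reference area
#' mask, and the "noise" distribution comes from a region outside visual
#' cortex. AUROC is computed per resample; a classification boundary is
#' fixed once on the *reference* VFS map (maximizing balanced accuracy)
#' and then applied unchanged to every trial-limited map, giving a
#' balanced accuracy per trial count and the smallest count with
#' sustained accuracy at or above the target.
#'
#' @param vfs_subsamples named list keyed by trial count; each entry a
#'   list of resamples carrying `$vfs` (from [subsample_average()] with
#'   elevation pairs).
#' @param reference_vfs the reference [visual_field_sign()] map.
#' @param signal_rois named list of logical masks, one per area, with the
#'   area's reference sign in `attr(roi, "sign")` (or supplied via
#'   `signs`).
#' @param noise_roi logical mask outside visual cortex; must not overlap
#'   any signal ROI and hold at least 20 px.
#' @param signs optional named numeric vector of area signs.
#' @param accuracy_target sustained balanced-accuracy criterion.
#' @return a list: `curves` data frame (`area, n, auroc, balanced_accuracy`),
#'   `trials_to_accuracy` named vector (NA if never reached), and
#'   `boundaries` (the per-area fixed boundaries).
#' @export
roc_detectability <- function(vfs_subsamples, reference_vfs, signal_rois,
                              noise_roi, signs = NULL, accuracy_target = 0.75) {
  for (nm in names(signal_rois)) {
    if (any(signal_rois[[nm]] & noise_roi))
      isi_stop("isimap_roc_error", "signal ROI '%s' overlaps the noise ROI", nm)
    if (sum(signal_rois[[nm]]) < 20 || sum(noise_roi) < 20)
      isi_stop("isimap_roc_error", "ROIs must hold at least 20 px")
  }
  get_sign <- function(nm) {
    s <- signs[[nm]] %||% attr(signal_rois[[nm]], "sign")
    if (is.null(s)) isi_stop("isimap_roc_error", "no reference sign for area '%s'", nm)
    s
  }
  boundaries <- vapply(names(signal_rois), function(nm) {
    sgn <- get_sign(nm)
    best_boundary(sgn * reference_vfs$s[signal_rois[[nm]]],
                  sgn * reference_vfs$s[noise_roi])
  }, numeric(1))
  ns <- as.integer(names(vfs_subsamples))
  rows <- list()
  for (k in seq_along(vfs_subsamples)) {
    for (nm in names(signal_rois)) {
      sgn <- get_sign(nm)
      stats_rep <- vapply(vfs_subsamples[[k]], function(r) {
        sig <- sgn * r$vfs$s[signal_rois[[nm]]]
        noi <- sgn * r$vfs$s[noise_roi]
        sig <- sig[is.finite(sig)]; noi <- noi[is.finite(noi)]
        if (!length(sig) || !length(noi)) return(c(NA_real_, NA_real_))
        b <- boundaries[nm]
        c(auroc(sig, noi),
          (mean(sig > b, na.rm = TRUE) + mean(noi <= b, na.rm = TRUE)) / 2)
      }, numeric(2))
      rows[[length(rows) + 1]] <- data.frame(
        area = nm, n = ns[k],
        auroc = mean(stats_rep[1, ], na.rm = TRUE),
        balanced_accuracy = mean(stats_rep[2, ], na.rm = TRUE))
    }
  }
  curves <- do.call(rbind, rows)
  tta <- vapply(names(signal_rois), function(nm) {
    cc <- curves[curves$area == nm, ]
    ord <- order(cc$n)
    pass <- cc$balanced_accuracy[ord] >= accuracy_target
    sustained <- rev(cumprod(rev(pass))) == 1
    if (any(sustained)) cc$n[ord][which(sustained)[1]] else NA_integer_
  }, numeric(1))
  list(curves = curves, trials_to_accuracy = tta, boundaries = boundaries,
       accuracy_target = accuracy_target)
}

#' Default noise region: outside all reference areas, eroded
#'
#' Pixels more than `margin` pixels (Manhattan distance) away from every
#' reference area mask.
#'
#' @param area_masks list of logical matrices.
#' @param margin erosion margin, pixels.
#' @return logical matrix.
#' @export
noise_roi_outside <- function(area_masks, margin = 10) {
  u <- Reduce(`|`, area_masks)
  dil <- u
  for (i in seq_len(margin)) {
    d <- dil
    d[-1, ] <- d[-1, ] | dil[-nrow(dil), ]
    d[-nrow(d), ] <- d[-nrow(d), ] | dil[-1, ]
    d[, -1] <- d[, -1] | dil[, -ncol(dil)]
    d[, -ncol(d)] <- d[, -ncol(d)] | dil[, -1]
    dil <- d
  }
  !dil
}

#' Pearson correlation between two aligned maps
#'
#' @param map_a,map_b [retinotopic_map()]s (or matrices) of equal shape;
#'   at least 10 jointly finite pixels required.
#' @return Pearson r over the jointly finite pixels.
#' @export
cross_session_correlation <- function(map_a, map_b) {
  a <- if (inherits(map_a, "retinotopic_map")) map_a$values else map_a
  b <- if (inherits(map_b, "retinotopic_map")) map_b$values else map_b
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10)
    isi_stop("isimap_stats_error", "need at least 10 jointly finite pixels")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    isi_stop("isimap_stats_error", "correlation undefined for a constant map")
  stats::cor(a[ok], b[ok])
}
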