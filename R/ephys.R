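# Validation of imaging-derived retinotopy against laminar LFP
# recordings, plus single-unit tuning summaries.

#' Construct a laminar LFP recording
#'
#' @param depths per-channel depth below the cortical surface,
#'   micrometers, strictly increasing.
#' @param responses channel x bar-position matrix of response
#'   magnitudes (non-negative).
#' @param latencies per-channel earliest visual response latency, ms.
#' @param positions bar positions, degrees, sorted ascending.
#' @param stimulus_width flashed-bar width, degrees.
#' @return an object of class `lfp_recording`.
#' @export
lfp_recording <- function(depths, responses, latencies, positions,
                          stimulus_width = 9) {
  if (any(diff(depths) <= 0))
    isi_stop("isimap_lfp_error", "channel depths must be strictly increasing")
  if (any(diff(positions) <= 0))
    isi_stop("isimap_lfp_error", "bar positions must be sorted ascending")
  if (nrow(responses) != length(depths) || ncol(responses) != length(positions))
    isi_stop("isimap_lfp_error", "response matrix must be channels x positions")
  if (any(responses < 0, na.rm = TRUE))
    isi_stop("isimap_lfp_error", "responses must be non-negative")
  structure(list(depths = as.numeric(depths), responses = responses,
                 latencies = as.numeric(latencies),
                 positions = as.numeric(positions),
                 stimulus_width = stimulus_width),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels (%g-%g um), %d bar positions\n",
              length(x$depths), min(x$depths), max(x$depths), length(x$positions)))
  invisible(x)
}

#' Read / write LFP recordings as long-format CSV
#'
#' Columns: `channel, depth_um, bar_position_deg, response, latency_ms`.
#' @param path CSV path.
#' @return an `lfp_recording`.
#' @export
read_lfp <- function(path) {
  d <- utils::read.csv(path)
  chans <- sort(unique(d$channel))
  positions <- sort(unique(d$bar_position_deg))
  resp <- matrix(NA_real_, length(chans), length(positions))
  depths <- latencies <- numeric(length(chans))
  for (i in seq_along(chans)) {
    di <- d[d$channel == chans[i], ]
    depths[i] <- di$depth_um[1]; latencies[i] <- di$latency_ms[1]
    resp[i, match(di$bar_position_deg, positions)] <- di$response
  }
  ord <- order(depths)
  lfp_recording(depths[ord], resp[ord, , drop = FALSE], latencies[ord], positions)
}

#' @rdname read_lfp
#' @param rec an `lfp_recording`.
#' @export
write_lfp <- function(rec, path) {
  long <- do.call(rbind, lapply(seq_along(rec$depths), function(i)
    data.frame(channel = i, depth_um = rec$depths[i],
               bar_position_deg = rec$positions,
               response = rec$responses[i, ],
               latency_ms = rec$latencies[i])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Assign channels to superficial / L4 / deep groups by latency
#'
#' The channel with the earliest visual response latency marks the
#' middle of layer 4; L4 is every channel within `l4_halfwidth`
#' (default 100 um, i.e. a ~200 um thick layer) of that depth.
#' Channels above are superficial, channels below are deep. A latency
#' tie is broken toward the shallower channel with a warning.
#'
#' @param rec an [lfp_recording()] with at least 3 channels.
#' @param l4_halfwidth half-thickness of L4, micrometers.
#' @return a list of class `layer_assignment`: `l4_center` (channel
#'   index), `superficial`, `l4`, `deep` (index vectors partitioning
#'   all channels).
#' @export
assign_layers <- function(rec, l4_halfwidth = 100) {
  if (length(rec$depths) < 3)
    isi_stop("isimap_lfp_error", "need at least 3 channels")
  if (any(!is.finite(rec$latencies)))
    isi_stop("isimap_lfp_error", "latencies must be finite")
  minima <- which(rec$latencies == min(rec$latencies))
  if (length(minima) > 1)
    isi_warn("latency tie across channels %s: using the shallowest",
             paste(minima, collapse = ", "))
  center <- minima[1]
  d0 <- rec$depths[center]
  l4 <- which(abs(rec$depths - d0) <= l4_halfwidth)
  structure(list(l4_center = center,
                 superficial = which(rec$depths < d0 - l4_halfwidth),
                 l4 = l4,
                 deep = which(rec$depths > d0 + l4_halfwidth)),
            class = "layer_assignment")
}

#' Preferred bar position of a channel group
#'
#' Averages the tuning curves over the group's channels *first*, then
#' takes the position of the maximum (averaging before the argmax, not
#' the other way round). Ties go to the position closest to the
#' response-weighted mean position.
#'
#' @param rec an [lfp_recording()].
#' @param group channel indices (e.g. from [assign_layers()]).
#' @return preferred position in degrees.
#' @export
lfp_preferred_position <- function(rec, group) {
  if (!length(group)) isi_stop("isimap_lfp_error", "channel group is empty")
  avg <- colMeans(rec$responses[group, , drop = FALSE])
  if (all(avg == 0)) isi_stop("isimap_lfp_error", "group shows no response")
  peak <- which(avg == max(avg))
  if (length(peak) > 1) {
    com <- sum(rec$positions * avg) / sum(avg)
    peak <- peak[which.min(abs(rec$positions[peak] - com))]
  }
  rec$positions[peak]
}

#' Agreement statistics between imaging and electrophysiology retinotopy
#'
#' @param expected,observed paired preferred positions in degrees (ISI
#'   prediction at the craniotomy vs LFP measurement), at least 3 pairs.
#' @param expected_el,observed_el optional second-axis pairs; when given,
#'   per-recording errors are combined as
#'   `sqrt(err_az^2 + err_el^2)`.
#' @return a list of class `validation_stats`: `r2` (squared Pearson r),
#'   `mean_abs_error`, `sd_abs_error` (degrees), `p_value` (two-sided
#'   Wilcoxon signed-rank of expected vs observed; 1 when all pairs
#'   agree exactly), `n`, and the pair table.
#' @export
isi_vs_lfp_stats <- function(expected, observed, expected_el = NULL,
                             observed_el = NULL) {
  if (length(expected) != length(observed) || length(expected) < 3)
    isi_stop("isimap_stats_error", "need >= 3 paired recordings")
  if (stats::sd(expected) == 0 || stats::sd(observed) == 0)
    isi_stop("isimap_stats_error", "correlation undefined for constant vectors")
  err <- abs(expected - observed)
  if (!is.null(expected_el))
    err <- sqrt((expected - observed)^2 + (expected_el - observed_el)^2)
  d <- observed - expected
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(expected, observed, paired = TRUE)$p.value)
  structure(list(r2 = stats::cor(expected, observed)^2,
                 mean_abs_error = mean(err), sd_abs_error = stats::sd(err),
                 p_value = p, n = length(expected),
                 pairs = data.frame(expected = expected, observed = observed,
                                    abs_error = err)),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("<validation_stats> n = %d, r2 = %.3f, |error| = %.2f +/- %.2f deg, p = %.3g\n",
              x$n, x$r2, x$mean_abs_error, x$sd_abs_error, x$p_value))
  invisible(x)
}

#' Single-unit tuning preferences and speed
#'
#' Determines the preferred drift direction from the direction-marginal
#' firing rate, then the preferred spatial and temporal frequency at
#' that direction; speed is `pref TF / pref SF` in degrees per second.
#' All-flat tables tie-break to the lowest parameter values with a
#' `tied` flag.
#'
#' @param rates data frame with columns `direction_deg, sf_cpd, tf_hz,
#'   rate_hz`, complete over the direction x SF x TF grid.
#' @return a list: `pref_direction`, `pref_sf`, `pref_tf`,
#'   `speed_deg_per_s`, `tied`.
#' @export
tuning_preferences <- function(rates) {
  need <- c("direction_deg", "sf_cpd", "tf_hz", "rate_hz")
  if (!all(need %in% names(rates)))
    isi_stop("isimap_tuning_error", "rates table must have columns %s",
             paste(need, collapse = ", "))
  if (any(is.na(rates$rate_hz))) {
    miss <- rates[is.na(rates$rate_hz), need[1:3]]
    isi_stop("isimap_tuning_error", "missing conditions: %s",
             paste(apply(miss, 1, paste, collapse = "/"), collapse = "; "))
  }
  dirs <- sort(unique(rates$direction_deg))
  dir_marg <- vapply(dirs, function(d) mean(rates$rate_hz[rates$direction_deg == d]),
                     numeric(1))
  tied <- length(unique(rates$rate_hz)) == 1
  pref_dir <- dirs[which.max(dir_marg)]          # which.max: first (lowest) on ties
  at_dir <- rates[rates$direction_deg == pref_dir, ]
  at_dir <- at_dir[order(at_dir$sf_cpd, at_dir$tf_hz), ]
  best <- at_dir[which.max(at_dir$rate_hz), ]
  list(pref_direction = pref_dir, pref_sf = best$sf_cpd, pref_tf = best$tf_hz,
       speed_deg_per_s = best$tf_hz / best$sf_cpd, tied = tied)
}

#' Compare tuning across areas (Kruskal-Wallis with Bonferroni post hoc)
#'
#' Thin statistical wrapper for tuning summaries pooled across areas;
#' effect interpretation is left to the user.
#'
#' @param values numeric vector of per-neuron tuning values (e.g. speed).
#' @param area factor or character vector of area labels.
#' @return a list: `kruskal` (htest), `posthoc` (pairwise Wilcoxon with
#'   Bonferroni correction, or NULL with < 3 groups).
#' @export
tuning_area_comparison <- function(values, area) {
  area <- factor(area)
  kw <- stats::kruskal.test(values, area)
  ph <- if (nlevels(area) >= 3)
    suppressWarnings(stats::pairwise.wilcox.test(values, area,
                                                 p.adjust.method = "bonferroni"))
  else NULL
  list(kruskal = kw, posthoc = ph)
}
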