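# Stimulus and pipeline configuration.

#' Stimulus configuration for periodic retinotopic mapping
#'
#' Describes the drifting contrast-reversing checkerboard bar used for
#' phase-encoded retinotopy. Defaults match the standard protocol: an 18 s
#' sweep (drift frequency 0.055 Hz), ten unidirectional sweeps per block,
#' a 20 degree wide bar, and coverage of -10 to 120 degrees in azimuth and
#' -30 to 30 degrees in elevation. Sweep directions are labelled
#' `NT`/`TN` (nasal-temporal and back; azimuth axis) and `IS`/`SI`
#' (inferior-superior and back; elevation axis).
#'
#' @param drift_freq stimulus drift frequency in Hz.
#' @param sweep_duration duration of one unidirectional sweep in seconds.
#' @param sweeps_per_block number of sweeps in one acquisition block.
#' @param bar_width bar width in degrees (metadata).
#' @param checker_reversal checkerboard contrast-reversal rate in Hz (metadata).
#' @param azimuth_span numeric length-2, azimuth coverage in degrees.
#' @param elevation_span numeric length-2, elevation coverage in degrees.
#' @param directions ordered sweep direction labels.
#' @param smooth_sigma Gaussian smoothing width for field-sign maps, pixels.
#' @param qc_threshold normalized-variance threshold for trial rejection.
#'
#' @return an object of class `stim_config`.
#' @export
stim_config <- function(drift_freq = 0.055,
                        sweep_duration = 18,
                        sweeps_per_block = 10,
                        bar_width = 20,
                        checker_reversal = 6,
                        azimuth_span = c(-10, 120),
                        elevation_span = c(-30, 30),
                        directions = c("NT", "TN", "IS", "SI"),
                        smooth_sigma = 4,
                        qc_threshold = 0.6) {
  cfg <- structure(list(
    drift_freq = drift_freq,
    sweep_duration = sweep_duration,
    sweeps_per_block = sweeps_per_block,
    bar_width = bar_width,
    checker_reversal = checker_reversal,
    azimuth_span = as.numeric(azimuth_span),
    elevation_span = as.numeric(elevation_span),
    directions = directions,
    smooth_sigma = smooth_sigma,
    qc_threshold = qc_threshold
  ), class = "stim_config")
  validate_stim_config(cfg)
  cfg
}

validate_stim_config <- function(cfg) {
  if (cfg$drift_freq <= 0 || cfg$sweep_duration <= 0)
    isi_stop("isimap_config_error", "drift_freq and sweep_duration must be positive")
  rel <- abs(cfg$drift_freq - 1 / cfg$sweep_duration) * cfg$sweep_duration
  if (rel > 0.02)
    isi_stop("isimap_config_error",
             "drift_freq (%.4g Hz) inconsistent with sweep_duration (%.4g s): 1/duration = %.4g Hz differs by %.1f%% (> 2%%)",
             cfg$drift_freq, cfg$sweep_duration, 1 / cfg$sweep_duration, 100 * rel)
  for (span in list(cfg$azimuth_span, cfg$elevation_span))
    if (length(span) != 2 || span[1] >= span[2])
      isi_stop("isimap_config_error", "spans must be length-2 with min < max")
  if (!all(c("NT", "TN", "IS", "SI") %in% cfg$directions))
    isi_stop("isimap_config_error", "directions must include NT, TN, IS, SI")
  invisible(cfg)
}

# axis bookkeeping: which directions form which retinotopic axis
direction_axis <- function(direction) {
  switch(direction,
         NT = , TN = "azimuth",
         IS = , SI = "elevation",
         isi_stop("isimap_config_error", "unknown direction '%s'", direction))
}

# forward member of each axis pair (forward azimuth: NT; forward elevation: IS)
is_forward <- function(direction) direction %in% c("NT", "IS")

opposing_direction <- function(direction) {
  switch(direction, NT = "TN", TN = "NT", IS = "SI", SI = "IS",
         isi_stop("isimap_config_error", "unknown direction '%s'", direction))
}

axis_span <- function(cfg, axis) {
  switch(axis, azimuth = cfg$azimuth_span, elevation = cfg$elevation_span,
         isi_stop("isimap_config_error", "unknown axis '%s'", axis))
}

#' Load a stimulus/pipeline configuration from YAML or JSON
#'
#' Unspecified fields take the documented defaults of [stim_config()].
#' Unknown keys produce a warning (not an error) so configs can carry
#' user metadata.
#'
#' @param path path to a YAML or JSON document; an empty document yields
#'   the full default configuration.
#' @return a validated `stim_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  } else {
    yaml::yaml.load(txt) %||% list()
  }
  known <- names(formals(stim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    isi_warn("ignoring unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(stim_config, vals[intersect(names(vals), known)])
}

#' Save a stimulus configuration to YAML
#'
#' @param cfg a `stim_config`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.stim_config <- function(x, ...) {
  cat(sprintf("<stim_config> drift %.3f Hz, sweep %g s, %d sweeps/block\n",
              x$drift_freq, x$sweep_duration, x$sweeps_per_block))
  cat(sprintf("  azimuth [%g, %g] deg, elevation [%g, %g] deg\n",
              x$azimuth_span[1], x$azimuth_span[2],
              x$elevation_span[1], x$elevation_span[2]))
  cat(sprintf("  smoothing sigma %g px, QC threshold %g\n",
              x$smooth_sigma, x$qc_threshold))
  invisible(x)
}
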