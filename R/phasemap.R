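# Fourier phase maps: per-trial responses at the drift frequency, trial
# quality control, averaging, hemodynamic delay correction, and
# conversion of phase to visual degrees.
#
# Phase convention. A phase map stores the complex response
#
#   z(x, y) = (2/N) * sum_t dA(x, y, t) * exp(+i * 2*pi*f * t)
#
# (the conjugate of the raw DFT coefficient, scaled by 2/N), so that for
# dA(t) = a * cos(2*pi*f*t - phi) the stored value is a * exp(i*phi):
# `Arg(z)` IS the temporal lag of the response at the drift frequency and
# `Mod(z)` is the cosine amplitude. All phases are wrapped to (-pi, pi].

#' Construct a phase map
#'
#' @param z complex matrix of per-pixel responses at the drift frequency.
#' @param direction sweep direction (`NT`, `TN`, `IS`, `SI`) or an axis
#'   label (`azimuth`, `elevation`) for delay-corrected maps.
#' @param n_trials number of trials aggregated.
#' @param pixel_scale micrometers per pixel.
#' @param drift_freq drift frequency, Hz.
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(z, direction, n_trials = 1L, pixel_scale = 6,
                      drift_freq = 0.055) {
  stopifnot(is.complex(z), is.matrix(z))
  structure(list(z = z, direction = direction, n_trials = as.integer(n_trials),
                 pixel_scale = pixel_scale, drift_freq = drift_freq),
            class = "phase_map")
}

#' Phase and amplitude of a phase map
#' @param map a `phase_map`.
#' @return matrix of phases in `(-pi, pi]` / non-negative amplitudes.
#' @export
map_phase <- function(map) wrap_phase(Arg(map$z))

#' @rdname map_phase
#' @export
map_amplitude <- function(map) Mod(map$z)

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %s, %d x %d px, %d trial(s)\n",
              x$direction, nrow(x$z), ncol(x$z), x$n_trials))
  invisible(x)
}

#' Extract one trial's complex response at the drift frequency
#'
#' Projects each pixel's absorbance trace onto the stimulus frequency by
#' an exact-frequency Fourier sum (not the nearest FFT bin, which would
#' miss 0.055 Hz for partial blocks):
#' `z = (2/N) * sum_k dA[k] * exp(i * 2*pi * f * (k-1) / frame_rate)`.
#'
#' @param absorbance an `absorbance_stack` from [compute_absorbance()].
#' @param frames frame indices of the trial *within the absorbance
#'   stack's frame axis*; default all frames.
#' @param drift_freq stimulus drift frequency, Hz.
#' @param frame_rate acquisition rate, Hz (default from the stack).
#' @param direction direction label attached to the result.
#' @return a [phase_map()].
#' @export
trial_phase_map <- function(absorbance, frames = NULL, drift_freq = 0.055,
                            frame_rate = absorbance$frame_rate,
                            direction = "NT") {
  da <- absorbance$delta_a
  if (is.null(frames)) frames <- seq_len(dim(da)[1])
  N <- length(frames)
  # one full stimulus cycle, with the same 2% slack the configuration
  # allows between drift_freq and 1/sweep_duration (18 s at 0.055 Hz is
  # 0.99 cycles and is the nominal protocol)
  if (N / frame_rate < 0.98 / drift_freq - 1e-9)
    isi_stop("isimap_phase_error",
             "trial spans %.2f s (< one full %.3f Hz stimulus cycle); need at least %d frames",
             N / frame_rate, drift_freq, ceiling(frame_rate / drift_freq))
  H <- dim(da)[2]; W <- dim(da)[3]
  flat <- matrix(da[frames, , , drop = FALSE], nrow = N)
  t_rel <- (seq_len(N) - 1) / frame_rate
  e <- exp(1i * 2 * pi * drift_freq * t_rel)
  z <- matrix(as.vector(e %*% flat) * (2 / N), H, W)
  phase_map(z, direction = direction,
            pixel_scale = absorbance$pixel_scale %||% 6,
            drift_freq = drift_freq)
}

#' Trial quality control by normalized map variance
#'
#' Scores each single-trial phase map by the spatial variance of its
#' amplitude map (within `roi` when given), normalized by the maximum
#' variance in the batch so that scores lie in `(0, 1]` with max exactly
#' 1. Trials scoring below `threshold` (default 0.6) are discarded:
#' signal-free trials produce flat, noise-only amplitude maps with low
#' spatial variance, while stimulus-driven trials show strong contrast
#' between responsive cortex and background.
#'
#' @param maps list of single-trial [phase_map()]s of equal shape.
#' @param threshold normalized-variance cutoff.
#' @param roi optional logical matrix restricting the statistic to the
#'   imaged region of interest.
#' @param statistic `"amplitude"` (spatial variance of the amplitude
#'   map, the default) or `"weighted_phase"` (variance of
#'   amplitude-weighted phase).
#' @return a list: `report` data frame (`trial, raw_var, norm_var,
#'   keep`), `kept` (the retained maps), `threshold`.
#' @export
trial_quality <- function(maps, threshold = 0.6, roi = NULL,
                          statistic = c("amplitude", "weighted_phase")) {
  statistic <- match.arg(statistic)
  if (!length(maps)) isi_stop("isimap_qc_error", "no trial maps supplied")
  raw <- vapply(maps, function(m) {
    v <- switch(statistic,
                amplitude = map_amplitude(m),
                weighted_phase = map_amplitude(m) * map_phase(m))
    if (!is.null(roi)) v <- v[roi]
    stats::var(as.vector(v), na.rm = TRUE)
  }, numeric(1))
  top <- max(raw, na.rm = TRUE)
  # a batch of identically flat maps has zero variance everywhere; score
  # them 0 rather than 0/0 so thresholding stays well defined
  norm <- if (is.finite(top) && top > 0) raw / top else rep(0, length(raw))
  norm[!is.finite(norm)] <- 0
  keep <- norm >= threshold
  if (!any(keep))
    isi_stop("isimap_qc_error",
             "all %d trials fall below the QC threshold %.2f; review the threshold",
             length(maps), threshold)
  list(report = data.frame(trial = seq_along(maps), raw_var = raw,
                           norm_var = norm, keep = keep),
       kept = maps[keep], threshold = threshold)
}

#' Average single-trial phase maps into a block or session map
#'
#' Per-pixel complex (vector) mean of the trial responses. Complex
#' averaging weights each trial's phase by its amplitude, which
#' down-weights noise-dominated pixels; it is the linear extension of the
#' per-trial Fourier projection.
#'
#' @param maps list of [phase_map()]s with a common direction and shape.
#' @return a [phase_map()] with `n_trials` equal to the total count.
#' @export
average_phase_maps <- function(maps) {
  if (!length(maps)) isi_stop("isimap_phase_error", "no maps to average")
  dirs <- unique(vapply(maps, `[[`, "", "direction"))
  if (length(dirs) != 1)
    isi_stop("isimap_phase_error", "cannot average maps of mixed directions: %s",
             paste(dirs, collapse = ", "))
  zsum <- Reduce(`+`, lapply(maps, `[[`, "z"))
  phase_map(zsum / length(maps), direction = dirs,
            n_trials = sum(vapply(maps, `[[`, 1L, "n_trials")),
            pixel_scale = maps[[1]]$pixel_scale,
            drift_freq = maps[[1]]$drift_freq)
}

#' Hemodynamic delay correction by opposing-direction combination
#'
#' The forward and backward sweeps share the retinotopic lag with
#' opposite sign and the hemodynamic delay with the same sign, so the
#' halved forward-minus-backward phase difference cancels the delay and
#' retains the retinotopic phase. Halving a wrapped difference leaves a
#' pi ambiguity; it is resolved with the common-delay estimate from the
#' forward-plus-backward sum (`delay = Arg(sum(w_f * w_b)) / 2`, a
#' single global value since the delay is a property of the acquisition,
#' not of the pixel), valid for delays up to half a stimulus period
#' (9 s at 0.055 Hz, comfortably covering the physiological 1-6 s).
#'
#' @param fwd,bwd [phase_map()]s of the opposing directions of one axis
#'   (`NT`/`TN` or `IS`/`SI`), same shape.
#' @param response_sign `-1` (default) when the response is a reflectance
#'   *decrease* (absorbance dip, the red-light hemodynamic signal); `+1`
#'   for positive-going responses.
#' @param delay_mode `"global"` (one delay for the map, robust) or
#'   `"pixel"` (per-pixel delay, for diagnostics).
#' @return a [phase_map()] whose phase is the retinotopic phase in
#'   `(-pi, pi]` (`0` maps to the sweep start position) and whose
#'   amplitude is the geometric mean of the two input amplitudes. The
#'   estimated delay is attached as attributes `delay_phase` (radians)
#'   and `delay_s` (seconds).
#' @export
absolute_phase <- function(fwd, bwd, response_sign = -1,
                           delay_mode = c("global", "pixel")) {
  delay_mode <- match.arg(delay_mode)
  if (!identical(dim(fwd$z), dim(bwd$z)))
    isi_stop("isimap_phase_error", "forward and backward maps differ in shape")
  if (fwd$direction %in% c("NT", "TN", "IS", "SI")) {
    if (opposing_direction(fwd$direction) != bwd$direction)
      isi_stop("isimap_phase_error", "directions %s and %s are not an opposing pair",
               fwd$direction, bwd$direction)
    axis <- direction_axis(fwd$direction)
    if (!is_forward(fwd$direction)) { tmp <- fwd; fwd <- bwd; bwd <- tmp }
  } else axis <- fwd$direction
  wf <- response_sign * fwd$z
  wb <- response_sign * bwd$z
  prod <- wf * wb                       # phase = lag_f + lag_b = 2*delay (mod 2*pi)
  delay2 <- if (delay_mode == "global") {
    s <- sum(prod[is.finite(prod)])
    matrix(mod_2pi(Arg(s)), nrow(wf), ncol(wf))
  } else mod_2pi(Arg(prod))
  theta <- mod_2pi(mod_2pi(Arg(wf)) - delay2 / 2)   # retinotopic lag in [0, 2*pi)
  amp <- sqrt(Mod(wf) * Mod(wb))
  out <- phase_map(amp * exp(1i * wrap_phase(theta)), direction = axis,
                   n_trials = fwd$n_trials + bwd$n_trials,
                   pixel_scale = fwd$pixel_scale, drift_freq = fwd$drift_freq)
  attr(out, "delay_phase") <- delay2[1, 1] / 2
  attr(out, "delay_s") <- delay2[1, 1] / 2 / (2 * pi * fwd$drift_freq)
  out
}

#' Construct a retinotopic map in visual degrees
#'
#' @param values matrix of preferred positions, degrees.
#' @param axis `"azimuth"` or `"elevation"`.
#' @param span length-2 coverage, degrees.
#' @param pixel_scale micrometers per pixel.
#' @param n_trials trials aggregated.
#' @return an object of class `retinotopic_map`.
#' @export
retinotopic_map <- function(values, axis, span, pixel_scale = 6, n_trials = 1L) {
  structure(list(values = values, axis = axis, span = as.numeric(span),
                 pixel_scale = pixel_scale, n_trials = as.integer(n_trials)),
            class = "retinotopic_map")
}

#' @export
print.retinotopic_map <- function(x, ...) {
  cat(sprintf("<retinotopic_map> %s [%g, %g] deg, %d x %d px, %d trial(s)\n",
              x$axis, x$span[1], x$span[2], nrow(x$values), ncol(x$values),
              x$n_trials))
  invisible(x)
}

#' Translate a delay-corrected phase map to visual degrees
#'
#' Maps one phase cycle linearly onto the axis span:
#' `position = span_start + (phase mod 2*pi) / (2*pi) * (span_end - span_start)`.
#' Pixels whose amplitude falls below the floor (default the 5th
#' percentile of the amplitude map) are set to `NaN`; published maps only
#' show responsive cortex.
#'
#' @param abs_map a delay-corrected [phase_map()] from [absolute_phase()].
#' @param cfg a [stim_config()].
#' @param axis `"azimuth"` or `"elevation"`; default taken from the map.
#' @param amplitude_floor quantile of the amplitude map below which
#'   pixels are masked (0 disables masking).
#' @return a [retinotopic_map()].
#' @export
phase_to_visual_degrees <- function(abs_map, cfg = stim_config(),
                                    axis = abs_map$direction,
                                    amplitude_floor = 0.05) {
  span <- axis_span(cfg, axis)
  pos <- span[1] + mod_2pi(map_phase(abs_map)) / (2 * pi) * (span[2] - span[1])
  if (amplitude_floor > 0) {
    amp <- map_amplitude(abs_map)
    pos[!(amp > stats::quantile(amp, amplitude_floor, na.rm = TRUE))] <- NaN
  }
  retinotopic_map(pos, axis = axis, span = span,
                  pixel_scale = abs_map$pixel_scale, n_trials = abs_map$n_trials)
}

#' Combine maps across sessions after alignment
#'
#' Each session's map is shifted into the reference frame by its
#' session-to-reference translation, then averaged: complex averaging
#' for phase maps, `NaN`-aware arithmetic averaging for degree maps
#' (degree values live on a non-circular span, so plain averaging is
#' safe once the phase has been unwrapped onto the span).
#'
#' @param maps list of [phase_map()]s or [retinotopic_map()]s of one axis.
#' @param shifts list of `c(dy, dx)` integer translations, one per map
#'   (e.g. from [register_translate()] on the session vasculature images).
#' @return a combined map of the same class with `n_trials` summed.
#' @export
combine_sessions <- function(maps, shifts = NULL) {
  if (!length(maps)) isi_stop("isimap_phase_error", "no session maps supplied")
  if (is.null(shifts)) shifts <- rep(list(c(0, 0)), length(maps))
  if (inherits(maps[[1]], "phase_map")) {
    zs <- lapply(seq_along(maps), function(i) {
      z <- maps[[i]]$z
      complex(real = apply_shift(Re(z), shifts[[i]]),
              imaginary = apply_shift(Im(z), shifts[[i]]))
    })
    acc <- Reduce(function(a, b) {
      s <- ifelse(is.na(a$z), 0, a$z) + ifelse(is.na(b), 0, b)
      list(z = s, n = a$n + !is.na(b))
    }, zs[-1], list(z = ifelse(is.na(zs[[1]]), 0, zs[[1]]), n = 0 + !is.na(zs[[1]])))
    z <- matrix(acc$z / pmax(acc$n, 1), nrow(maps[[1]]$z))
    z[acc$n == 0] <- NA
    phase_map(z, direction = maps[[1]]$direction,
              n_trials = sum(vapply(maps, `[[`, 1L, "n_trials")),
              pixel_scale = maps[[1]]$pixel_scale, drift_freq = maps[[1]]$drift_freq)
  } else {
    vs <- lapply(seq_along(maps), function(i) apply_shift(maps[[i]]$values, shifts[[i]]))
    cnt <- Reduce(`+`, lapply(vs, function(v) !is.na(v)))
    tot <- Reduce(`+`, lapply(vs, function(v) ifelse(is.na(v), 0, v)))
    out <- tot / pmax(cnt, 1)
    out[cnt == 0] <- NaN
    retinotopic_map(out, axis = maps[[1]]$axis, span = maps[[1]]$span,
                    pixel_scale = maps[[1]]$pixel_scale,
                    n_trials = sum(vapply(maps, `[[`, 1L, "n_trials")))
  }
}

#' Process one block: absorbance then per-trial phase maps
#'
#' Convenience wrapper chaining [compute_absorbance()] and
#' [trial_phase_map()] over the sweep-trials of one block.
#'
#' @param stack an [image_stack()] covering one block.
#' @param trials a `trial_set` from [segment_trials()].
#' @param cfg a [stim_config()].
#' @param baseline_window baseline window in seconds for
#'   [compute_absorbance()].
#' @return list of single-trial [phase_map()]s, in trial order.
#' @export
process_block <- function(stack, trials, cfg = stim_config(),
                          baseline_window = c(0, 5)) {
  ab <- compute_absorbance(stack, baseline_window = baseline_window)
  lapply(seq_len(nrow(trials)), function(i) {
    trial_phase_map(ab, frames = trials$first_frame[i]:trials$last_frame[i],
                    drift_freq = cfg$drift_freq, frame_rate = stack$frame_rate,
                    direction = trials$direction[i])
  })
}
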