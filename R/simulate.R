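# Synthetic-data generator: ground-truth retinotopic layouts, reflectance
# movies, vasculature images, and laminar LFP responses.
#
# Signal model. A pixel whose preferred position lies a fraction x along
# the sweep axis responds when the bar crosses it, i.e. with temporal lag
# x * sweep_duration for the forward sweep and (1 - x) * sweep_duration
# for the backward sweep, plus the hemodynamic delay tau. The response is
# a reflectance *decrease* (a dip), so the absorbance trace of a
# responsive pixel during one sweep is
#
#   dA(t) = -a * cos(2*pi*f*t - (2*pi*x + 2*pi*f*tau))        (forward)
#
# with a set by the modulation amplitude. Bad trials carry the same
# baseline and noise but no stimulus-locked component, so they cannot be
# detected from brightness alone.

#' Simulation parameters
#'
#' Defaults place the generator in the regime the pipeline is designed
#' for: modulation well under 1% of baseline reflectance, a 1-6 s
#' hemodynamic delay, correlated 1/f background fluctuations of the same
#' order as the evoked dip, and ~10% signal-free trials.
#'
#' @param image_size image side in pixels (square images).
#' @param pixel_scale micrometers per pixel.
#' @param frame_rate camera rate, Hz.
#' @param n_blocks blocks per direction.
#' @param baseline mean baseline intensity, camera units.
#' @param modulation peak fractional reflectance modulation of responsive
#'   pixels (0.004 = 0.8% peak-to-trough).
#' @param white_sd per-frame, per-pixel white noise SD as a fraction of
#'   baseline.
#' @param pink_sd SD of the spatially correlated 1/f background, as a
#'   fraction of baseline.
#' @param pink_grid side of the coarse spatial grid carrying the 1/f
#'   background (shared across nearby pixels).
#' @param bad_trial_fraction probability that a sweep carries no signal.
#' @param baseline_s pre-stimulus baseline recorded at the start of each
#'   block, seconds.
#' @param seed root seed; fixes all randomness of the simulation.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(image_size = 128, pixel_scale = 6, frame_rate = 10,
                       n_blocks = 5, baseline = 40000, modulation = 0.004,
                       white_sd = 0.005, pink_sd = 0.002, pink_grid = 12,
                       bad_trial_fraction = 0.1, baseline_s = 5, seed = 1) {
  p <- list(image_size = image_size, pixel_scale = pixel_scale,
            frame_rate = frame_rate, n_blocks = n_blocks, baseline = baseline,
            modulation = modulation, white_sd = white_sd, pink_sd = pink_sd,
            pink_grid = pink_grid, bad_trial_fraction = bad_trial_fraction,
            baseline_s = baseline_s, seed = seed)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))))
  if (p$modulation > 0.05)
    isi_warn("modulation %.3g exceeds 0.05: outside the small-signal regime", p$modulation)
  structure(p, class = "sim_params")
}

#' Specify one simulated cortical area
#'
#' Each area is an elliptical cortical patch carrying an affine map from
#' pixel position to visual-field position. `sign` is the target visual
#' field sign (the sign of the Jacobian determinant of the cortex to
#' visual-field mapping under image coordinates: row down, col right);
#' it is realised by mirroring the azimuth gradient.
#'
#' @param name area label.
#' @param center `(row, col)` ellipse center, pixels (0-based).
#' @param semiaxes `(row, col)` ellipse semi-axes, pixels.
#' @param az_range,el_range visual-field coverage of the area, degrees.
#' @param sign target field sign, `+1` or `-1`.
#' @return a list of class `area_spec`.
#' @export
area_spec <- function(name, center, semiaxes, az_range, el_range, sign = 1) {
  stopifnot(sign %in% c(-1, 1), length(center) == 2, length(semiaxes) == 2)
  structure(list(name = name, center = as.numeric(center),
                 semiaxes = as.numeric(semiaxes),
                 az_range = as.numeric(az_range), el_range = as.numeric(el_range),
                 sign = as.integer(sign)),
            class = "area_spec")
}

# the standard mouse layout: V1 plus five higher visual areas, with field
# sign alternating across shared retinotopic borders; coordinates are
# fractions of the image side
six_area_layout <- function(image_size) {
  S <- image_size
  mk <- function(name, cy, cx, ay, ax, az, el, sg)
    area_spec(name, c(cy, cx) * S, c(ay, ax) * S, az, el, sg)
  list(
    mk("V1", 0.66, 0.50, 0.22, 0.20, c(0, 110), c(-25, 25), +1),
    mk("LM", 0.42, 0.20, 0.10, 0.09, c(0, 90),  c(-20, 20), -1),
    mk("AL", 0.28, 0.38, 0.09, 0.08, c(0, 60),  c(-15, 20), +1),
    mk("RL", 0.22, 0.58, 0.08, 0.08, c(0, 50),  c(-10, 25), -1),
    mk("AM", 0.22, 0.78, 0.08, 0.07, c(20, 70), c(-10, 25), +1),
    mk("PM", 0.42, 0.80, 0.09, 0.08, c(30, 100), c(-20, 20), -1)
  )
}

single_area_layout <- function(image_size) {
  S <- image_size
  list(area_spec("V1", c(0.5, 0.5) * S, c(0.35, 0.35) * S,
                 c(0, 110), c(-25, 25), +1))
}

#' Build a ground-truth retinotopic layout
#'
#' Computes per-pixel true azimuth and elevation from each area's affine
#' cortex-to-visual-field mapping (`NaN` outside all areas), plus the
#' per-area field signs and masks the pipeline is expected to recover.
#'
#' @param layout `"six_area"`, `"single"`, or a list of [area_spec()].
#' @param image_size image side in pixels.
#' @param cfg a [stim_config()]; area coverages must lie inside its spans.
#' @param hemodynamic_delay hemodynamic lag in seconds (1-6 s regime).
#' @param pixel_scale micrometers per pixel.
#' @return an object of class `ground_truth` with fields `azimuth_true`,
#'   `elevation_true` (matrices, degrees), `areas` (list with `name`,
#'   `mask`, `sign`, `centroid_px`), `mask` (union of areas),
#'   `hemodynamic_delay`, `image_size`, `pixel_scale`.
#' @export
make_ground_truth <- function(layout = "six_area", image_size = 128,
                              cfg = stim_config(), hemodynamic_delay = 2,
                              pixel_scale = 6) {
  specs <- if (is.character(layout)) {
    switch(layout,
           six_area = six_area_layout(image_size),
           single = single_area_layout(image_size),
           isi_stop("isimap_layout_error", "unknown layout preset '%s'", layout))
  } else layout
  H <- W <- image_size
  rows <- matrix(0:(H - 1), H, W)          # 0-based, row increases downward
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  az <- matrix(NA_real_, H, W); el <- matrix(NA_real_, H, W)
  covered <- matrix(FALSE, H, W)
  areas <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    a <- specs[[i]]
    if (any(a$az_range < cfg$azimuth_span[1] - 1e-9) ||
        any(a$az_range > cfg$azimuth_span[2] + 1e-9) ||
        any(a$el_range < cfg$elevation_span[1] - 1e-9) ||
        any(a$el_range > cfg$elevation_span[2] + 1e-9))
      isi_stop("isimap_layout_error",
               "area '%s' visual-field range exceeds the configured spans", a$name)
    if (a$center[1] - a$semiaxes[1] < 0 || a$center[1] + a$semiaxes[1] > H - 1 ||
        a$center[2] - a$semiaxes[2] < 0 || a$center[2] + a$semiaxes[2] > W - 1)
      isi_stop("isimap_layout_error", "area '%s' does not fit in the image", a$name)
    inside <- ((rows - a$center[1]) / a$semiaxes[1])^2 +
              ((cols - a$center[2]) / a$semiaxes[2])^2 <= 1
    if (any(inside & covered)) {
      clash <- vapply(areas[seq_len(i - 1)],
                      function(p) !is.null(p) && any(p$mask & inside), logical(1))
      isi_stop("isimap_layout_error", "area '%s' overlaps area(s): %s", a$name,
               paste(vapply(areas[which(clash)], `[[`, "", "name"), collapse = ", "))
    }
    covered <- covered | inside
    az_mid <- mean(a$az_range); az_half <- diff(a$az_range) / 2
    el_mid <- mean(a$el_range); el_half <- diff(a$el_range) / 2
    # azimuth along columns (mirrored when sign = +1 so that the Jacobian
    # determinant sign(d az/d row * d el/d col - d az/d col * d el/d row)
    # equals the requested sign), elevation along rows
    s_az <- -a$sign
    az[inside] <- az_mid + s_az * (cols[inside] - a$center[2]) / a$semiaxes[2] * az_half
    el[inside] <- el_mid + (rows[inside] - a$center[1]) / a$semiaxes[1] * el_half
    areas[[i]] <- list(name = a$name, mask = inside, sign = a$sign,
                       centroid_px = c(row = a$center[1], col = a$center[2]),
                       az_range = a$az_range, el_range = a$el_range)
  }
  structure(list(azimuth_true = az, elevation_true = el, areas = areas,
                 mask = covered, hemodynamic_delay = hemodynamic_delay,
                 image_size = image_size, pixel_scale = pixel_scale,
                 area_names = vapply(areas, `[[`, "", "name")),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %dx%d px, %d areas (%s), delay %g s\n",
              x$image_size, x$image_size, length(x$areas),
              paste(x$area_names, collapse = ", "), x$hemodynamic_delay))
  invisible(x)
}

# true retinotopic phase in [0, 2*pi): fraction along the axis span
true_phase <- function(gt, cfg, axis) {
  span <- axis_span(cfg, axis)
  val <- if (axis == "azimuth") gt$azimuth_true else gt$elevation_true
  2 * pi * (val - span[1]) / (span[2] - span[1])
}

# temporal lag (radians of the stimulus cycle) of each pixel for a sweep
# in the given direction, including the hemodynamic delay
sweep_lag <- function(gt, cfg, direction) {
  theta <- true_phase(gt, cfg, direction_axis(direction))
  if (!is_forward(direction)) theta <- 2 * pi - theta
  theta + 2 * pi * cfg$drift_freq * gt$hemodynamic_delay
}

# 1/f temporal trace: white noise shaped by 1/sqrt(f) in the Fourier domain
pink_trace <- function(n) {
  if (n < 4) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1)
  f <- f / sqrt(freq)
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  y / stats::sd(y)
}

# bilinear upsample of a coarse g x g x n array of traces to H x W per frame
upsample_grid <- function(coarse, H, W) {
  g <- dim(coarse)[1]
  # map pixel centers onto the coarse grid
  ry <- seq(1, g, length.out = H); rx <- seq(1, g, length.out = W)
  y0 <- pmin(floor(ry), g - 1); x0 <- pmin(floor(rx), g - 1)
  wy <- ry - y0; wx <- rx - x0
  n <- dim(coarse)[3]
  out <- array(0, dim = c(n, H, W))
  for (k in seq_len(n)) {
    cc <- coarse[, , k]
    a <- cc[cbind(rep(y0, W), rep(x0, each = H))]
    b <- cc[cbind(rep(y0 + 1, W), rep(x0, each = H))]
    d <- cc[cbind(rep(y0, W), rep(x0 + 1, each = H))]
    e <- cc[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
    wyv <- rep(wy, W); wxv <- rep(wx, each = H)
    out[k, , ] <- matrix((1 - wyv) * (1 - wxv) * a + wyv * (1 - wxv) * b +
                         (1 - wyv) * wxv * d + wyv * wxv * e, H, W)
  }
  out
}

#' Simulate one acquisition block as a reflectance movie
#'
#' Generates a `baseline_s` pre-stimulus segment followed by
#' `cfg$sweeps_per_block` unidirectional sweeps. Responsive pixels carry a
#' sinusoidal reflectance dip at the drift frequency whose temporal phase
#' encodes their true retinotopic position plus the hemodynamic delay;
#' signal-free ("bad") sweeps are drawn with probability
#' `params$bad_trial_fraction` and differ from good sweeps only in the
#' absence of the stimulus-locked component. Output is deterministic for
#' a given `(params, seed)`.
#'
#' @param gt a [make_ground_truth()] object.
#' @param params a [sim_params()].
#' @param cfg a [stim_config()].
#' @param direction sweep direction for the whole block.
#' @param seed block seed (defaults to `params$seed`); vary it across
#'   blocks.
#' @param block_id integer id recorded in the event table.
#' @param keep_signal if `TRUE`, attach the noiseless absorbance signal
#'   array as element `signal` (used by consistency checks).
#' @return a list with `stack` (an [image_stack()]), `events`
#'   (an [event_table()]), `trials` (a `trial_set`), `bad_sweeps`
#'   (logical per sweep), and optionally `signal`.
#' @export
simulate_movie <- function(gt, params, cfg = stim_config(), direction = "NT",
                           seed = params$seed, block_id = 1L,
                           keep_signal = FALSE) {
  if (!direction %in% cfg$directions)
    isi_stop("isimap_config_error", "direction '%s' not in configuration", direction)
  H <- W <- gt$image_size
  fr <- params$frame_rate
  n_sweeps <- cfg$sweeps_per_block
  t_total <- params$baseline_s + n_sweeps * cfg$sweep_duration
  n <- ceiling(t_total * fr - 1e-9)   # cover the whole block
  times <- (seq_len(n) - 1) / fr
  onsets <- params$baseline_s + (seq_len(n_sweeps) - 1) * cfg$sweep_duration

  lag <- sweep_lag(gt, cfg, direction)          # H x W, NaN outside areas
  amp_a <- log10(1 + params$modulation)         # absorbance amplitude of the dip
  resp <- gt$mask

  with_seed(seed, {
    bad <- stats::runif(n_sweeps) < params$bad_trial_fraction
    # stimulus-locked absorbance signal
    signal <- array(0, dim = c(n, H, W))
    lag_v <- lag[resp]
    for (s in seq_len(n_sweeps)) {
      if (bad[s]) next
      idx <- which(times >= onsets[s] & times < onsets[s] + cfg$sweep_duration)
      trel <- times[idx] - onsets[s]
      # outer product: frames x responsive pixels
      ph <- outer(2 * pi * cfg$drift_freq * trel, lag_v, `-`)
      block <- -amp_a * cos(ph)
      flat <- matrix(0, length(idx), H * W)
      flat[, which(resp)] <- block
      signal[idx, , ] <- array(flat, dim = c(length(idx), H, W))
    }
    # noise: white per pixel-frame + spatially shared 1/f background
    frames <- params$baseline * 10^signal
    if (params$white_sd > 0)
      frames <- frames * (1 + array(stats::rnorm(n * H * W, sd = params$white_sd),
                                    dim = c(n, H, W)))
    if (params$pink_sd > 0) {
      g <- params$pink_grid
      coarse <- array(0, dim = c(g, g, n))
      for (i in seq_len(g)) for (j in seq_len(g))
        coarse[i, j, ] <- pink_trace(n)
      pink <- upsample_grid(aperm(coarse, c(1, 2, 3)), H, W)
      frames <- frames * (1 + params$pink_sd * pink)
    }
  })

  stack <- image_stack(frames, frame_rate = fr, wavelength_tag = "red",
                       pixel_scale = params$pixel_scale)
  events <- event_table(onset_s = onsets, offset_s = onsets + cfg$sweep_duration,
                        direction = rep(direction, n_sweeps), block = block_id)
  trials <- segment_trials(stack, events, cfg)
  out <- list(stack = stack, events = events, trials = trials,
              bad_sweeps = bad, direction = direction, block_id = block_id)
  if (keep_signal) out$signal <- signal
  out
}

#' Simulate a vasculature reference image
#'
#' Produces a deterministic image with dark curvilinear vessel-like
#' structures over a smooth background, suitable as registration texture
#' (its autocorrelation has a unique global peak).
#'
#' @param image_size image side in pixels (at least 64).
#' @param seed integer seed.
#' @return a numeric matrix in arbitrary intensity units.
#' @export
simulate_vasculature <- function(image_size = 128, seed = 1) {
  if (image_size < 64)
    isi_stop("isimap_layout_error", "vasculature image must be at least 64x64")
  H <- W <- image_size
  with_seed(seed, {
    img <- matrix(1, H, W)
    # gentle illumination gradient
    img <- img * outer(seq(0.95, 1.05, length.out = H),
                       seq(1.03, 0.97, length.out = W))
    n_vessels <- max(12, round(image_size / 6))
    for (v in seq_len(n_vessels)) {
      y <- stats::runif(1, 1, H); x <- stats::runif(1, 1, W)
      ang <- stats::runif(1, 0, 2 * pi)
      width <- stats::runif(1, 0.8, 2.2)
      depth <- stats::runif(1, 0.25, 0.5)
      for (s in seq_len(round(1.6 * image_size))) {
        ang <- ang + stats::rnorm(1, sd = 0.25)
        y <- y + sin(ang); x <- x + cos(ang)
        if (y < 2 || y > H - 1 || x < 2 || x > W - 1) break
        r0 <- max(1, floor(y - 2 * width)); r1 <- min(H, ceiling(y + 2 * width))
        c0 <- max(1, floor(x - 2 * width)); c1 <- min(W, ceiling(x + 2 * width))
        rr <- r0:r1; cc <- c0:c1
        d2 <- outer((rr - y)^2, (cc - x)^2, `+`)
        img[rr, cc] <- img[rr, cc] * (1 - depth * exp(-d2 / (2 * width^2)))
      }
    }
    img + matrix(stats::rnorm(H * W, sd = 0.01), H, W)
  })
}

#' Simulate laminar LFP responses to flashed bars
#'
#' Models a single-shank probe spanning the cortical depth at a
#' craniotomy. Each channel's response across bar positions is a unimodal
#' tuning curve centered on the ground-truth azimuth at the craniotomy
#' plus depth-dependent retinotopic scatter: every channel carries
#' independent per-channel scatter (`scatter_superficial`), and the
#' channels below `l4_depth` additionally share one per-recording offset
#' of SD `scatter_deep`, modelling the systematic retinotopic divergence
#' of the deep population (a shared offset does not average out across
#' channels, unlike per-channel jitter). Response latency is minimal at
#' `l4_depth` and grows away from it (slightly faster above than below,
#' so the minimum is unique when `l4_depth` sits on a channel).
#'
#' @param gt a [make_ground_truth()] object.
#' @param craniotomy_center `(row, col)` pixel position; must fall inside
#'   a ground-truth area.
#' @param n_channels number of probe channels.
#' @param spacing channel spacing, micrometers.
#' @param l4_depth depth of the layer-4 latency minimum, micrometers.
#' @param bar_positions stimulus bar centers, degrees azimuth.
#' @param scatter_superficial SD of independent per-channel retinotopic
#'   scatter, degrees (all channels).
#' @param scatter_deep SD of the shared deep-population offset, degrees
#'   (channels below `l4_depth`).
#' @param tuning_width Gaussian tuning SD, degrees.
#' @param noise_sd additive response noise (fraction of peak).
#' @param seed integer seed.
#' @return an object of class `lfp_recording` (see [lfp_recording()])
#'   with a `manifest` attribute recording the true azimuth, probe span
#'   and per-channel tuning centers.
#' @export
simulate_lfp <- function(gt, craniotomy_center, n_channels = 32, spacing = 25,
                         l4_depth = 400, bar_positions = seq(-60, 150, by = 9),
                         scatter_superficial = 2, scatter_deep = 6,
                         tuning_width = 12, noise_sd = 0.05, seed = 1) {
  r <- round(craniotomy_center[1]) + 1L; c <- round(craniotomy_center[2]) + 1L
  if (r < 1 || c < 1 || r > gt$image_size || c > gt$image_size ||
      !gt$mask[r, c])
    isi_stop("isimap_sim_error",
             "craniotomy center (%g, %g) lies outside all ground-truth areas",
             craniotomy_center[1], craniotomy_center[2])
  az_true <- gt$azimuth_true[r, c]
  depths <- spacing * seq_len(n_channels)
  # latency: V-shaped around L4, asymmetric so the minimum is unique
  latency <- 40 + ifelse(depths <= l4_depth,
                         0.05 * (l4_depth - depths),
                         0.07 * (depths - l4_depth))
  with_seed(seed, {
    centers <- az_true + scatter_superficial * stats::rnorm(n_channels)
    centers[depths > l4_depth] <- centers[depths > l4_depth] +
      scatter_deep * stats::rnorm(1)
    resp <- outer(centers, bar_positions,
                  function(cen, pos) exp(-(pos - cen)^2 / (2 * tuning_width^2)))
    if (noise_sd > 0)
      resp <- resp + matrix(stats::rnorm(length(resp), sd = noise_sd),
                            nrow = n_channels)
    resp <- pmax(resp, 0)
  })
  rec <- lfp_recording(depths = depths, responses = resp, latencies = latency,
                       positions = bar_positions, stimulus_width = 9)
  attr(rec, "manifest") <- list(azimuth_true = az_true,
                                probe_span_um = spacing * (n_channels - 1),
                                l4_depth = l4_depth, centers = centers,
                                craniotomy_center = craniotomy_center)
  rec
}
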