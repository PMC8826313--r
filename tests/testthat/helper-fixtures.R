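# Shared fixtures. Expensive objects are built once per test run and
# memoised; all tests that need the full study-regime session reuse the
# same one.
#
# Problem sizes are scaled down from the nominal protocol so the suite
# runs in minutes: a 96 px field at 2.5 Hz instead of >= 128 px at 10 Hz.
# The scaling preserves the quantities that matter (cycles per sweep,
# modulation depth, noise-to-signal ratio, trials per session); see the
# methods vignette.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# nominal stimulus protocol (18 s sweeps at 0.055 Hz)
nominal_cfg <- function(...) stim_config(smooth_sigma = 1.5, ...)

# exact-cycle protocol for phase-precision tests: 20 s sweeps at 0.05 Hz
# sampled at 2.5 Hz give exactly 50 frames per stimulus cycle, so the
# Fourier projection has no spectral leakage
exact_cfg <- function(...) stim_config(drift_freq = 0.05, sweep_duration = 20,
                                       smooth_sigma = 1.5, ...)

# scaled-down acquisition in the study regime (default noise, 10% bad
# trials); 10 blocks per direction ~ a long session of 100 sweep-trials
study_params <- function(...) sim_params(image_size = 96, frame_rate = 2.5,
                                         n_blocks = 10, seed = 7, ...)

noiseless_params <- function(image_size = 96, ...)
  sim_params(image_size = image_size, frame_rate = 2.5, n_blocks = 1,
             white_sd = 0, pink_sd = 0, bad_trial_fraction = 0, seed = 3, ...)

# the full noisy study session plus everything derived from it
study_fixture <- function() fixture("study", function() {
  cfg <- nominal_cfg()
  gt <- make_ground_truth("six_area", 96, cfg, hemodynamic_delay = 3)
  session <- simulate_session(gt, study_params(), cfg, seed = 7)
  paired <- qc_and_pair(session, threshold = cfg$qc_threshold)
  az <- build_axis_map(paired$pairs_az, cfg)
  el <- build_axis_map(paired$pairs_el, cfg)
  vfs <- visual_field_sign(az, el, cfg$smooth_sigma)
  rois <- lapply(gt$areas, `[[`, "mask")
  names(rois) <- vapply(gt$areas, `[[`, "", "name")
  list(cfg = cfg, gt = gt, session = session, paired = paired,
       az = az, el = el, vfs = vfs, rois = rois,
       signs = stats::setNames(vapply(gt$areas, `[[`, 0, "sign"), names(rois)))
})

# one noiseless session under the nominal protocol
noiseless_fixture <- function() fixture("noiseless", function() {
  cfg <- nominal_cfg()
  gt <- make_ground_truth("six_area", 96, cfg, hemodynamic_delay = 3)
  session <- simulate_session(gt, noiseless_params(), cfg, seed = 3)
  paired <- qc_and_pair(session, threshold = NULL)
  list(cfg = cfg, gt = gt, paired = paired)
})

# a tiny single-area noiseless session for cheap end-to-end checks
tiny_fixture <- function() fixture("tiny", function() {
  cfg <- exact_cfg()
  gt <- make_ground_truth("single", 64, cfg, hemodynamic_delay = 2)
  params <- noiseless_params(image_size = 64)
  session <- simulate_session(gt, params, cfg, seed = 5)
  paired <- qc_and_pair(session, threshold = NULL)
  list(cfg = cfg, gt = gt, params = params, session = session, paired = paired)
})

# brute-force single-pixel Fourier projection used as the DFT oracle
oracle_projection <- function(trace, drift_freq, frame_rate) {
  n <- length(trace)
  t_rel <- (seq_len(n) - 1) / frame_rate
  (2 / n) * sum(trace * exp(1i * 2 * pi * drift_freq * t_rel))
}

# threshold-sweep AUROC oracle: empirical ROC traced over all cutoffs,
# integrated by trapezoids
oracle_auroc <- function(signal, noise) {
  signal <- signal[is.finite(signal)]; noise <- noise[is.finite(noise)]
  cuts <- sort(unique(c(signal, noise, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) mean(signal >= ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(noise >= ct), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
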