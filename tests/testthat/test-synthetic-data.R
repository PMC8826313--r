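# Ground-truth layouts, movie generator, vasculature and LFP simulators.

test_that("ground truth builds disjoint areas with the requested signs", {
  cfg <- nominal_cfg()
  gt <- make_ground_truth("six_area", 96, cfg)
  expect_equal(gt$area_names, c("V1", "LM", "AL", "RL", "AM", "PM"))
  expect_equal(vapply(gt$areas, `[[`, 0L, "sign"), c(1L, -1L, 1L, -1L, 1L, -1L))
  overlap <- Reduce(`+`, lapply(gt$areas, function(a) a$mask * 1))
  expect_lte(max(overlap), 1)
  expect_equal(gt$mask, overlap > 0)
  # coverage stays inside the configured spans, NaN outside all areas
  expect_true(all(is.na(gt$azimuth_true[!gt$mask])))
  rng <- range(gt$azimuth_true, na.rm = TRUE)
  expect_gte(rng[1], cfg$azimuth_span[1])
  expect_lte(rng[2], cfg$azimuth_span[2])
})

test_that("the true Jacobian sign matches each area's declared sign", {
  gt <- make_ground_truth("six_area", 96, nominal_cfg())
  for (a in gt$areas) {
    ctr <- round(a$centroid_px) + 1
    # central differences on the true maps at the area center
    daz_dc <- (gt$azimuth_true[ctr[1], ctr[2] + 1] - gt$azimuth_true[ctr[1], ctr[2] - 1]) / 2
    daz_dr <- (gt$azimuth_true[ctr[1] + 1, ctr[2]] - gt$azimuth_true[ctr[1] - 1, ctr[2]]) / 2
    del_dc <- (gt$elevation_true[ctr[1], ctr[2] + 1] - gt$elevation_true[ctr[1], ctr[2] - 1]) / 2
    del_dr <- (gt$elevation_true[ctr[1] + 1, ctr[2]] - gt$elevation_true[ctr[1] - 1, ctr[2]]) / 2
    jac <- daz_dr * del_dc - daz_dc * del_dr
    expect_equal(sign(jac), a$sign, info = a$name)
  }
})

test_that("impossible layouts are rejected", {
  cfg <- nominal_cfg()
  expect_error(make_ground_truth("nope", 96, cfg), class = "isimap_layout_error")
  overlapping <- list(
    area_spec("A", c(32, 32), c(10, 10), c(0, 50), c(-10, 10), 1),
    area_spec("B", c(36, 36), c(10, 10), c(0, 50), c(-10, 10), -1))
  expect_error(make_ground_truth(overlapping, 64, cfg),
               class = "isimap_layout_error")
  outside <- list(area_spec("A", c(5, 5), c(10, 10), c(0, 50), c(-10, 10), 1))
  expect_error(make_ground_truth(outside, 64, cfg), class = "isimap_layout_error")
  wide <- list(area_spec("A", c(32, 32), c(10, 10), c(0, 200), c(-10, 10), 1))
  expect_error(make_ground_truth(wide, 64, cfg), class = "isimap_layout_error")
})

test_that("simulated movies have the right frame count and determinism", {
  tf <- tiny_fixture()
  # noisy parameters, so a different seed must yield a different movie
  params <- sim_params(image_size = 64, frame_rate = 2.5, n_blocks = 1,
                       seed = 11)
  sim1 <- simulate_movie(tf$gt, params, tf$cfg, direction = "NT", seed = 11)
  sim2 <- simulate_movie(tf$gt, params, tf$cfg, direction = "NT", seed = 11)
  sim3 <- simulate_movie(tf$gt, params, tf$cfg, direction = "NT", seed = 12)
  n_expect <- ceiling((params$baseline_s +
                       tf$cfg$sweeps_per_block * tf$cfg$sweep_duration) *
                      params$frame_rate)
  expect_equal(dim(sim1$stack$frames)[1], n_expect)
  expect_identical(sim1$stack$frames, sim2$stack$frames)
  expect_false(identical(sim1$stack$frames, sim3$stack$frames))
  expect_equal(nrow(sim1$trials), tf$cfg$sweeps_per_block)
})

test_that("bad sweeps carry no stimulus-locked signal; good sweeps do", {
  cfg <- exact_cfg()
  gt <- make_ground_truth("single", 64, cfg)
  params <- sim_params(image_size = 64, frame_rate = 2.5, n_blocks = 1,
                       white_sd = 0, pink_sd = 0, bad_trial_fraction = 0.5,
                       seed = 21)
  sim <- simulate_movie(gt, params, cfg, seed = 21, keep_signal = TRUE)
  expect_true(any(sim$bad_sweeps) && any(!sim$bad_sweeps))
  for (s in seq_along(sim$bad_sweeps)) {
    idx <- sim$trials$first_frame[s]:sim$trials$last_frame[s]
    energy <- sum(abs(sim$signal[idx, , ]))
    if (sim$bad_sweeps[s]) expect_equal(energy, 0)
    else expect_gt(energy, 0)
  }
})

test_that("the modulation stays in the sub-percent regime", {
  tf <- tiny_fixture()
  sim <- simulate_movie(tf$gt, tf$params, tf$cfg, seed = 2)
  dev <- abs(sim$stack$frames / tf$params$baseline - 1)
  expect_lt(max(dev), 0.01)          # < 1% peak deviation
  expect_gt(max(dev), 0.5 * tf$params$modulation)  # the dip is present
})

test_that("the planted temporal lag follows the signal model", {
  # a single responsive pixel: lag_fwd = 2*pi*x + 2*pi*f*tau
  cfg <- exact_cfg()
  gt <- make_ground_truth("single", 64, cfg, hemodynamic_delay = 2)
  params <- noiseless_params(image_size = 64)
  sim <- simulate_movie(gt, params, cfg, direction = "NT", seed = 1,
                        keep_signal = TRUE)
  px <- which(gt$mask, arr.ind = TRUE)[1, ]
  idx <- sim$trials$first_frame[1]:sim$trials$last_frame[1]
  z <- oracle_projection(sim$signal[idx, px[1], px[2]], cfg$drift_freq,
                         params$frame_rate)
  span <- cfg$azimuth_span
  x <- (gt$azimuth_true[px[1], px[2]] - span[1]) / diff(span)
  # the first frame inside the trial samples the sweep a fraction of a
  # frame period after its onset; that sampling offset advances the
  # apparent phase and must enter the closed form
  t0 <- sim$stack$timestamps[sim$trials$first_frame[1]] - sim$events$onset_s[1]
  expected_lag <- 2 * pi * x + 2 * pi * cfg$drift_freq *
    (gt$hemodynamic_delay - t0)
  # stored response is a dip: -a*cos(wt - lag) projects to phase lag + pi
  expect_equal(wrap_phase(Arg(z)), wrap_phase(expected_lag + pi), tolerance = 1e-9)
  expect_equal(Mod(z), log10(1 + params$modulation), tolerance = 1e-9)
})

test_that("vasculature images are deterministic and registrable textures", {
  v1 <- simulate_vasculature(64, seed = 4)
  v2 <- simulate_vasculature(64, seed = 4)
  expect_identical(v1, v2)
  expect_error(simulate_vasculature(32), class = "isimap_layout_error")
  expect_gt(stats::sd(v1), 0.01)  # actual structure, not a flat field
})

test_that("simulated LFP places the latency minimum at the L4 channel", {
  tf <- tiny_fixture()
  ctr <- tf$gt$areas[[1]]$centroid_px
  rec <- simulate_lfp(tf$gt, ctr, n_channels = 24, spacing = 25,
                      l4_depth = 400, seed = 9)
  expect_s3_class(rec, "lfp_recording")
  expect_equal(rec$depths[which.min(rec$latencies)], 400)
  man <- attr(rec, "manifest")
  expect_equal(man$azimuth_true,
               tf$gt$azimuth_true[round(ctr[1]) + 1, round(ctr[2]) + 1])
  expect_error(simulate_lfp(tf$gt, c(0, 0)), class = "isimap_sim_error")
})

test_that("session simulation is seed-deterministic across blocks", {
  cfg <- exact_cfg()
  gt <- make_ground_truth("single", 64, cfg)
  params <- sim_params(image_size = 64, frame_rate = 2.5, n_blocks = 2, seed = 31)
  s1 <- simulate_session(gt, params, cfg, directions = "NT", seed = 31)
  s2 <- simulate_session(gt, params, cfg, directions = "NT", seed = 31)
  expect_identical(lapply(s1$maps$NT, `[[`, "z"), lapply(s2$maps$NT, `[[`, "z"))
  expect_equal(length(s1$maps$NT), 2 * cfg$sweeps_per_block)
  # different blocks see different noise
  expect_false(identical(s1$maps$NT[[1]]$z, s1$maps$NT[[11]]$z))
})
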