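# Configuration, stacks, events, trial segmentation, file round trips.

test_that("default configuration encodes the standard protocol", {
  cfg <- stim_config()
  expect_equal(cfg$drift_freq, 0.055)
  expect_equal(cfg$sweep_duration, 18)
  expect_equal(cfg$sweeps_per_block, 10)
  expect_equal(cfg$azimuth_span, c(-10, 120))
  expect_equal(cfg$elevation_span, c(-30, 30))
  expect_setequal(cfg$directions, c("NT", "TN", "IS", "SI"))
})

test_that("inconsistent drift frequency and sweep duration are rejected", {
  expect_error(stim_config(drift_freq = 0.08, sweep_duration = 18),
               class = "isimap_config_error")
  expect_error(stim_config(drift_freq = -1), class = "isimap_config_error")
  expect_error(stim_config(azimuth_span = c(5, -5)), class = "isimap_config_error")
  # 2% slack: 0.055 Hz vs 18 s (0.99 cycles) is legal
  expect_s3_class(stim_config(drift_freq = 0.055, sweep_duration = 18),
                  "stim_config")
})

test_that("configs round-trip through YAML and JSON with defaults filled", {
  cfg <- stim_config(drift_freq = 0.05, sweep_duration = 20, smooth_sigma = 2)
  yml <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, yml)
  expect_equal(load_config(yml), cfg)

  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"drift_freq": 0.05, "sweep_duration": 20}', jsn)
  cfg2 <- load_config(jsn)
  expect_equal(cfg2$drift_freq, 0.05)
  expect_equal(cfg2$sweeps_per_block, stim_config()$sweeps_per_block)

  prt <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("drift_freq: 0.05", "sweep_duration: 20", "operator: someone"), prt)
  expect_warning(cfg3 <- load_config(prt), "unknown config keys")
  expect_equal(cfg3$drift_freq, 0.05)
})

test_that("image stacks validate their metadata", {
  fr <- array(1, dim = c(4, 3, 3))
  expect_error(image_stack(matrix(1, 3, 3), 10), class = "isimap_stack_error")
  expect_error(image_stack(fr, frame_rate = -2), class = "isimap_config_error")
  expect_error(image_stack(fr, 10, timestamps = c(0, 1, 1, 2)),
               class = "isimap_stack_error")
  expect_error(image_stack(fr, 10, timestamps = c(0, 1)),
               class = "isimap_stack_error")
  expect_error(image_stack(fr, 10, pixel_scale = 0), class = "isimap_stack_error")
  st <- image_stack(fr, 10)
  expect_equal(st$timestamps, (0:3) / 10)
})

test_that("integer stacks round-trip losslessly through TIFF", {
  fr <- array(sample.int(65535, 5 * 8 * 8, replace = TRUE), dim = c(5, 8, 8))
  st <- image_stack(fr, frame_rate = 2.5, wavelength_tag = "green",
                    pixel_scale = 12)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_identical(st2$frames, fr + 0)  # numeric, exact
  expect_equal(st2$frame_rate, 2.5)
  expect_equal(st2$wavelength_tag, "green")
  expect_equal(st2$pixel_scale, 12)
  expect_equal(st2$timestamps, st$timestamps)
})

test_that("non-integer stacks round-trip through float TIFF to 32-bit precision", {
  fr <- array(rnorm(4 * 6 * 6, mean = 1000, sd = 200), dim = c(4, 6, 6))
  st <- image_stack(fr, frame_rate = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  # float32 mantissa ~ 2^-24 relative on the [0, 1] encoded values
  expect_lt(max(abs(st2$frames - fr)) / diff(range(fr)), 1e-6)
})

test_that("reading requires the sidecar and an existing file", {
  expect_error(read_stack(file.path(tempdir(), "nope.tif")),
               class = "isimap_read_error")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), path)
  expect_error(read_stack(path), class = "isimap_config_error")
})

test_that("single images round-trip with their affine encoding", {
  img <- matrix(rnorm(64, 5000, 300), 8, 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  expect_lt(max(abs(read_image(path) - img)) / diff(range(img)), 1e-6)
})

test_that("event tables validate, sort and round-trip as CSV", {
  expect_error(event_table(5, 5, "NT"), class = "isimap_event_error")
  ev <- event_table(c(25, 5), c(45, 25), c("TN", "NT"), block = c(1, 1))
  expect_equal(ev$direction, c("NT", "TN"))  # sorted by onset
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  expect_equal(read_events(path), ev)
})

test_that("trial segmentation assigns each frame to at most one sweep", {
  # 2 x 2 px movie so the arithmetic dominates, 10 Hz, two sweeps of 18 s
  n <- 10 * (5 + 2 * 18)
  st <- image_stack(array(1, dim = c(n, 2, 2)), frame_rate = 10)
  ev <- event_table(c(5, 23), c(23, 41), c("NT", "TN"))
  tr <- segment_trials(st, ev)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$n_frames, c(180, 180))
  # half-open [onset, offset): frame at t = 23 s belongs to the second sweep
  expect_equal(tr$first_frame[2], tr$last_frame[1] + 1)
  expect_equal(attr(tr, "unassigned_frames"), n - 360)
})

test_that("segmentation flags empty sweeps and rejects out-of-range ones", {
  st <- image_stack(array(1, dim = c(100, 2, 2)), frame_rate = 10)
  ev <- event_table(c(1, 2.02, 3), c(2, 2.05, 4), c("NT", "TN", "NT"))
  expect_warning(tr <- segment_trials(st, ev), "caught no frames")
  expect_equal(nrow(tr), 2)
  expect_equal(attr(tr, "empty_sweeps"), 2L)

  ev_bad <- event_table(5, 30, "NT")
  expect_error(segment_trials(st, ev_bad), class = "isimap_segmentation_error")
  expect_error(segment_trials(st, event_table(1, 2, "XX")),
               class = "isimap_event_error")
})

test_that("a sweep ending one frame period past the last timestamp is legal", {
  # 45 frames at 2.5 Hz span [0, 17.6] s; an 18 s sweep is fully sampled
  st <- image_stack(array(1, dim = c(45, 2, 2)), frame_rate = 2.5)
  tr <- segment_trials(st, event_table(0, 18, "NT"))
  expect_equal(tr$n_frames, 45)
})
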