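# Fourier phase maps, QC, averaging, delay correction, degree conversion.

make_absorbance <- function(traces, frame_rate) {
  # traces: frames x pixels matrix -> absorbance_stack-shaped object
  n <- nrow(traces); p <- ncol(traces)
  da <- array(traces, dim = c(n, p, 1))
  structure(list(delta_a = da, frame_rate = frame_rate, pixel_scale = 6,
                 timestamps = (seq_len(n) - 1) / frame_rate,
                 frames = seq_len(n)),
            class = "absorbance_stack")
}

test_that("the exact-frequency projection matches the brute-force oracle", {
  set.seed(42)
  f <- 0.05; fr <- 2.5; n <- 50
  traces <- matrix(rnorm(n * 9), n, 9)
  ab <- make_absorbance(traces, fr)
  pm <- trial_phase_map(ab, drift_freq = f, frame_rate = fr)
  for (k in 1:9) {
    zo <- oracle_projection(traces[, k], f, fr)
    expect_equal(pm$z[k, 1], zo, tolerance = 1e-9)
  }
})

test_that("a planted cosine is recovered with exact phase and amplitude", {
  f <- 0.05; fr <- 2.5; n <- 50
  t_ <- (seq_len(n) - 1) / fr
  for (phi in c(-2.5, -0.4, 0, 1.1, 3)) {
    tr <- matrix(0.8 * cos(2 * pi * f * t_ - phi), n, 1)
    pm <- trial_phase_map(make_absorbance(tr, fr), drift_freq = f, frame_rate = fr)
    expect_equal(map_phase(pm)[1, 1], wrap_phase(phi), tolerance = 1e-9)
    expect_equal(map_amplitude(pm)[1, 1], 0.8, tolerance = 1e-9)
  }
})

test_that("trials shorter than a stimulus cycle are rejected", {
  ab <- make_absorbance(matrix(0, 30, 1), 2.5)  # 12 s < 0.98/0.055
  expect_error(trial_phase_map(ab, drift_freq = 0.055, frame_rate = 2.5),
               class = "isimap_phase_error")
  # 45 frames at 2.5 Hz = 18 s = 0.99 cycles: the nominal protocol, legal
  ab2 <- make_absorbance(matrix(0, 45, 1), 2.5)
  expect_s3_class(trial_phase_map(ab2, drift_freq = 0.055, frame_rate = 2.5),
                  "phase_map")
})

test_that("trial QC separates structured from flat amplitude maps", {
  mk <- function(amp) phase_map(matrix(complex(modulus = amp, argument = 0), 4, 4),
                                "NT")
  structured <- phase_map(matrix(complex(modulus = c(rep(1, 8), rep(0.1, 8)),
                                         argument = 0), 4, 4), "NT")
  flat <- mk(0.5)
  q <- trial_quality(list(structured, structured, flat), threshold = 0.6)
  expect_equal(q$report$keep, c(TRUE, TRUE, FALSE))
  expect_equal(max(q$report$norm_var), 1)
  expect_length(q$kept, 2)
  expect_error(trial_quality(list(flat, flat), threshold = 2),
               class = "isimap_qc_error")
  expect_error(trial_quality(list()), class = "isimap_qc_error")
})

test_that("averaging is the complex mean and refuses mixed directions", {
  z1 <- matrix(complex(real = 1, imaginary = 1), 2, 2)
  z2 <- matrix(complex(real = 3, imaginary = -1), 2, 2)
  m <- average_phase_maps(list(phase_map(z1, "NT"), phase_map(z2, "NT")))
  expect_equal(m$z, (z1 + z2) / 2)
  expect_equal(m$n_trials, 2L)
  expect_error(average_phase_maps(list(phase_map(z1, "NT"), phase_map(z2, "TN"))),
               class = "isimap_phase_error")
})

test_that("delay correction solves the textbook forward/backward case", {
  # positive-going response with phase theta forward, -theta backward:
  # the retinotopic phase is theta and the delay is 0
  theta <- 0.9
  fwd <- phase_map(matrix(complex(modulus = 1, argument = theta), 2, 2), "NT")
  bwd <- phase_map(matrix(complex(modulus = 1, argument = -theta), 2, 2), "TN")
  am <- absolute_phase(fwd, bwd, response_sign = +1)
  expect_equal(map_phase(am)[1, 1], theta, tolerance = 1e-12)
  expect_equal(attr(am, "delay_phase"), 0, tolerance = 1e-12)
})

test_that("delay correction recovers a known common delay", {
  # lag_f = theta + d, lag_b = (2*pi - theta) + d
  theta <- c(0.5, 2.0, 4.0, 5.5); d <- 1.2
  fwd <- phase_map(matrix(complex(modulus = 1, argument = wrap_phase(theta + d)),
                          2, 2), "NT")
  bwd <- phase_map(matrix(complex(modulus = 1,
                                  argument = wrap_phase(2 * pi - theta + d)),
                          2, 2), "TN")
  am <- absolute_phase(fwd, bwd, response_sign = +1)
  expect_equal(attr(am, "delay_phase"), d, tolerance = 1e-9)
  expect_equal(mod_2pi(map_phase(am)), matrix(theta, 2, 2), tolerance = 1e-9)
  # passing the arguments swapped (bwd first) must give the same answer
  am2 <- absolute_phase(bwd, fwd, response_sign = +1)
  expect_equal(am2$z, am$z, tolerance = 1e-12)
})

test_that("delay correction validates its inputs", {
  a <- phase_map(matrix(complex(modulus = 1, argument = 0), 2, 2), "NT")
  b <- phase_map(matrix(complex(modulus = 1, argument = 0), 3, 3), "TN")
  expect_error(absolute_phase(a, b), class = "isimap_phase_error")
  c_ <- phase_map(matrix(complex(modulus = 1, argument = 0), 2, 2), "IS")
  expect_error(absolute_phase(a, c_), class = "isimap_phase_error")
})

test_that("degrees map linearly onto the axis span", {
  cfg <- nominal_cfg()
  phases <- c(0, pi / 2, pi, 3 * pi / 2)
  am <- phase_map(matrix(complex(modulus = 1, argument = phases), 2, 2),
                  "azimuth")
  m <- phase_to_visual_degrees(am, cfg, amplitude_floor = 0)
  span <- cfg$azimuth_span
  expect_equal(as.vector(m$values), span[1] + c(0, 0.25, 0.5, 0.75) * diff(span),
               tolerance = 1e-12)
  # elevation uses its own span
  am_el <- phase_map(matrix(complex(modulus = 1, argument = pi), 1, 1), "elevation")
  m_el <- phase_to_visual_degrees(am_el, cfg, amplitude_floor = 0)
  expect_equal(m_el$values[1, 1], 0)  # middle of [-30, 30]
})

test_that("the amplitude floor masks weak pixels only", {
  amp <- c(1, 1, 1, 0.001)
  am <- phase_map(matrix(complex(modulus = amp, argument = 1), 2, 2), "azimuth")
  m <- phase_to_visual_degrees(am, nominal_cfg(), amplitude_floor = 0.3)
  expect_equal(sum(is.nan(m$values)), 1)
  expect_true(is.nan(m$values[2, 2]))
})

test_that("session maps combine with shifts and NaN-aware averaging", {
  a <- retinotopic_map(matrix(1, 3, 3), "azimuth", c(-10, 120))
  b <- retinotopic_map(matrix(3, 3, 3), "azimuth", c(-10, 120))
  comb <- combine_sessions(list(a, b), shifts = list(c(0, 0), c(1, 0)))
  expect_equal(comb$values[2, 2], 2)      # overlap: mean of 1 and 3
  expect_equal(comb$values[1, 1], 1)      # only session A covers row 1
  z <- matrix(complex(real = 1, imaginary = 2), 2, 2)
  pm <- combine_sessions(list(phase_map(z, "NT"), phase_map(z, "NT")))
  expect_equal(pm$z, z)
})
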