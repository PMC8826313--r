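# Resampling, error curves, AUROC, detectability, map correlation.

test_that("rank-based AUROC equals the threshold-sweep oracle", {
  set.seed(7)
  for (rep in 1:5) {
    sig <- rnorm(40, mean = rep * 0.3)
    noi <- rnorm(55)
    expect_equal(auroc(sig, noi), oracle_auroc(sig, noi), tolerance = 1e-12)
  }
  # with ties
  sig <- c(1, 1, 2, 3); noi <- c(0, 1, 1, 2)
  expect_equal(auroc(sig, noi), oracle_auroc(sig, noi), tolerance = 1e-12)
})

test_that("AUROC hits its analytic anchors", {
  expect_equal(auroc(c(2, 3, 4), c(-1, 0, 1)), 1)
  expect_equal(auroc(c(-1, 0, 1), c(2, 3, 4)), 0)
  expect_equal(auroc(c(1, 2), c(1, 2)), 0.5)
  expect_equal(auroc(c(NA, 2, 3), c(0, 1, NaN)), 1)  # non-finite dropped
})

test_that("map correlation equals the covariance-formula oracle", {
  set.seed(11)
  a <- matrix(rnorm(100), 10, 10)
  b <- 0.6 * a + matrix(rnorm(100, sd = 0.5), 10, 10)
  a[3, 5] <- NaN; b[7, 2] <- NaN
  ok <- is.finite(a) & is.finite(b)
  x <- a[ok]; y <- b[ok]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cross_session_correlation(a, b), oracle, tolerance = 1e-12)
  expect_error(cross_session_correlation(a[1:2, 1:2], b[1:2, 1:2]),
               class = "isimap_stats_error")
  expect_error(cross_session_correlation(matrix(1, 5, 5), matrix(rnorm(25), 5, 5)),
               class = "isimap_stats_error")
})

test_that("subsampling is deterministic in the seed and validates n", {
  tf <- tiny_fixture()
  s1 <- subsample_average(tf$paired$pairs_az, 3, n_reps = 2, seed = 9,
                          cfg = tf$cfg)
  s2 <- subsample_average(tf$paired$pairs_az, 3, n_reps = 2, seed = 9,
                          cfg = tf$cfg)
  expect_equal(s1[[1]]$indices, s2[[1]]$indices)
  expect_equal(s1[[2]]$map$values, s2[[2]]$map$values)
  expect_error(subsample_average(tf$paired$pairs_az, 99, cfg = tf$cfg),
               class = "isimap_resample_error")
  expect_error(subsample_average(tf$paired$pairs_az, 2, n_reps = 0, cfg = tf$cfg),
               class = "isimap_resample_error")
  # with replacement, n beyond the pool is legal
  s3 <- subsample_average(tf$paired$pairs_az, 12, n_reps = 1,
                          with_replacement = TRUE, seed = 1, cfg = tf$cfg)
  expect_length(s3[[1]]$indices, 12)
})

test_that("the error curve is zero against an identically built reference", {
  tf <- tiny_fixture()
  np <- length(tf$paired$pairs_az)
  ref <- build_axis_map(tf$paired$pairs_az, tf$cfg)
  subs <- list(subsample_average(tf$paired$pairs_az, 2, n_reps = 3, seed = 2,
                                 cfg = tf$cfg))
  names(subs) <- "2"
  subs[[as.character(np)]] <- subsample_average(tf$paired$pairs_az, np,
                                                n_reps = 1, seed = 2, cfg = tf$cfg)
  curve <- centroid_error_curve(subs, ref)
  expect_s3_class(curve, "error_curve")
  expect_equal(curve$mean_um[curve$n == np], 0)
  expect_gte(curve$mean_um[curve$n == 2], 0)
})

test_that("the trial criterion requires a sustained crossing", {
  curve <- structure(data.frame(n = c(2, 5, 10, 20),
                                mean_um = c(150, 80, 120, 60)),
                     class = c("error_curve", "data.frame"))
  n_star <- min_trials_for_criterion(curve, 100)
  expect_equal(as.integer(n_star), 20L)  # the lucky dip at n = 5 does not count
  curve$mean_um <- c(150, 140, 130, 120)
  miss <- min_trials_for_criterion(curve, 100)
  expect_true(is.na(miss))
  expect_equal(attr(miss, "status"), "not reached")
  expect_error(min_trials_for_criterion(curve[1, , drop = FALSE], 100),
               class = "isimap_resample_error")
})

test_that("the noise ROI sits outside all areas with the requested margin", {
  m <- matrix(FALSE, 40, 40); m[15:25, 15:25] <- TRUE
  roi <- noise_roi_outside(list(m), margin = 5)
  expect_false(any(roi & m))
  expect_false(roi[14, 20])  # within the margin
  expect_false(roi[30, 20])
  expect_true(roi[5, 5])
  expect_true(roi[31 + 5, 20])
})

test_that("detectability fixes its boundary on the reference map", {
  set.seed(3)
  H <- 30
  s_ref <- matrix(rnorm(H * H, 0, 0.05), H, H)
  roi <- matrix(FALSE, H, H); roi[5:14, 5:14] <- TRUE
  s_ref[roi] <- s_ref[roi] - 0.8            # negative-sign area
  noise_roi <- matrix(FALSE, H, H); noise_roi[20:29, 20:29] <- TRUE
  vfs_ref <- structure(list(s = s_ref, sigma = 0, pixel_scale = 6, n_trials = 1L),
                       class = "vfs_map")
  reps <- lapply(1:3, function(i) {
    s <- s_ref + matrix(rnorm(H * H, 0, 0.05), H, H)
    list(vfs = structure(list(s = s, sigma = 0, pixel_scale = 6, n_trials = 1L),
                         class = "vfs_map"))
  })
  out <- roc_detectability(list("4" = reps), vfs_ref, list(A = roi), noise_roi,
                           signs = c(A = -1))
  expect_gt(out$curves$auroc, 0.99)
  expect_gt(out$curves$balanced_accuracy, 0.95)
  expect_equal(unname(out$trials_to_accuracy["A"]), 4)
  # overlapping ROIs and missing signs are refused
  expect_error(roc_detectability(list("4" = reps), vfs_ref, list(A = roi), roi,
                                 signs = c(A = -1)),
               class = "isimap_roc_error")
  expect_error(roc_detectability(list("4" = reps), vfs_ref, list(A = roi),
                                 noise_roi),
               class = "isimap_roc_error")
})
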