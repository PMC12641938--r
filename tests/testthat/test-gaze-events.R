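# Event detection: confidence filtering, I-DT fixations, saccades, blinks.

test_that("confidence filtering keeps exactly the qualifying samples", {
  s <- const_stream(1)
  expect_identical(nrow(filter_by_confidence(s, 0)), nrow(s))

  half <- const_stream(1, conf = 0.5)
  expect_identical(nrow(filter_by_confidence(half, 1)), 0L)

  withr::with_seed(11, {
    conf <- runif(500)
    t <- seq(0, by = 0.005, length.out = 500)
    s <- gaze_stream(t, rnorm(500), rnorm(500), conf)
  })
  f <- filter_by_confidence(s, 0.6)
  expect_equal(nrow(f), sum(conf >= 0.6))   # linear-scan oracle
  expect_false(is.unsorted(f$timestamp, strictly = TRUE))
})

test_that("angular dispersion equals the brute-force pairwise maximum", {
  expect_equal(angular_dispersion(1.2, -3), 0)
  expect_equal(angular_dispersion(c(0, 1), c(0, 0)), 1)
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(2:25, 1)
      x <- rnorm(n, sd = 2); y <- rnorm(n, sd = 2)
      expect_equal(angular_dispersion(x, y), brute_dispersion(x, y))
    }
  })
})

test_that("I-DT recovers stationary dwells and enforces duration bounds", {
  # 200 ms stationary dwell -> exactly one fixation with zero dispersion
  fx <- detect_fixations(const_stream(0.200))
  expect_identical(nrow(fx), 1L)
  expect_equal(fx$duration, 0.200)
  expect_equal(fx$dispersion, 0)

  # 50 ms dwell is below the 80 ms floor
  expect_identical(nrow(detect_fixations(const_stream(0.050))), 0L)

  # a 1 s dwell splits into capped fixations plus a kept remainder
  fx <- detect_fixations(const_stream(1.0))
  expect_identical(nrow(fx), 3L)
  expect_true(all(fx$duration <= 0.420 + 1e-9))
  expect_equal(sum(fx$n_samples), 201)

  # empty stream and unsorted timestamps
  expect_identical(nrow(detect_fixations(const_stream(1)[0, ])), 0L)
  bad <- const_stream(0.2)
  bad$timestamp <- rev(bad$timestamp)
  expect_error(detect_fixations(bad), "increasing")
})

test_that("temporal gaps from removed samples break fixation windows", {
  # two 150 ms dwells at the same position, separated by a 20 ms gap:
  # dispersion alone cannot split them, the gap must
  a <- const_stream(0.150)
  b <- const_stream(0.150, t0 = 0.150 + 0.020)
  s <- gaze_stream(c(a$timestamp, b$timestamp), c(a$x_deg, b$x_deg),
                   c(a$y_deg, b$y_deg), c(a$confidence, b$confidence))
  fx <- detect_fixations(s)
  expect_identical(nrow(fx), 2L)
  expect_equal(fx$duration, c(0.150, 0.150))
})

test_that("raising max_dispersion never sheds absorbed samples (uncapped)", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- 400
      t <- seq(0, by = 0.005, length.out = n)
      x <- cumsum(rnorm(n, sd = 0.3))
      y <- cumsum(rnorm(n, sd = 0.3))
      s <- gaze_stream(t, x, y, rep(1, n))
      absorbed <- vapply(c(0.5, 1, 1.5, 2.5, 4, 8), function(d) {
        sum(detect_fixations(s, max_dispersion = d,
                             max_duration = Inf)$n_samples)
      }, numeric(1))
      expect_true(all(diff(absorbed) >= 0))
    }
  })
})

test_that("saccades pair consecutive fixations with centroid amplitudes", {
  fx <- fake_fixations(start = c(0, 0.21), end = c(0.2, 0.41),
                       cx = c(0, 0.3), cy = c(0, 0))
  sc <- extract_saccades(fx)
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$amplitude, 0.3)
  expect_equal(sc$duration, 0.01)

  # n fixations -> n - 1 saccades when every pair counts
  n <- 8
  fx <- fake_fixations(start = (0:(n - 1)) * 0.5,
                       end = (0:(n - 1)) * 0.5 + 0.2,
                       cx = rnorm(n), cy = rnorm(n))
  expect_identical(nrow(extract_saccades(fx, max_gap = Inf)),
                   as.integer(n - 1))

  # pairs separated by long gaps are not saccades at the default
  fx <- fake_fixations(start = c(0, 0.9), end = c(0.2, 1.1),
                       cx = c(0, 1), cy = c(0, 0))
  expect_identical(nrow(extract_saccades(fx)), 0L)
  expect_identical(nrow(extract_saccades(fx[1, ])), 0L)
})

test_that("blinks are maximal sub-floor confidence runs of enough span", {
  expect_identical(nrow(detect_blinks(const_stream(2))), 0L)

  s <- const_stream(1)
  drop_idx <- s$timestamp >= 0.4 & s$timestamp < 0.6
  s$confidence[drop_idx] <- 0
  bl <- detect_blinks(s, confidence_floor = 0.5, min_duration = 0.1)
  expect_identical(nrow(bl), 1L)
  expect_equal(bl$start, 0.4)

  # short dropouts below min_duration are ignored
  s2 <- const_stream(1)
  s2$confidence[10:12] <- 0
  expect_identical(nrow(detect_blinks(s2, 0.5, 0.1)), 0L)
})

test_that("session metrics aggregate events with NA sentinels when empty", {
  none <- detect_fixations(const_stream(0.05))
  sm <- session_metrics(none, extract_saccades(none),
                        detect_blinks(const_stream(1)), 60)
  expect_identical(sm$fixation_count, 0L)
  expect_true(is.na(sm$mean_fixation_duration))
  expect_true(is.na(sm$mean_saccade_amplitude))
  expect_equal(sm$blink_rate, 0)

  fx <- fake_fixations(start = c(0, 0.3, 0.6), end = c(0.2, 0.5, 0.9),
                       cx = c(0, 1, 1), cy = c(0, 0, 2))
  sc <- extract_saccades(fx, max_gap = Inf)
  bl <- data.frame(start = 1, end = 1.2, duration = 0.2)
  sm <- session_metrics(fx, sc, bl, 120)
  expect_equal(sm$fixation_count, 3L)
  expect_equal(sm$mean_fixation_duration, mean(c(0.2, 0.2, 0.3)))
  expect_equal(sm$mean_saccade_amplitude, mean(c(1, 2)))
  expect_equal(sm$blink_rate, 1 / 2)

  expect_error(session_metrics(fx, sc, bl, 0), "total_duration")
})

test_that("detector closes the loop on generated sessions", {
  prof <- study_profiles()$attending
  # noise-free: exact closure of counts and durations
  p0 <- expertise_profile(
    label = "noiseless", mean_fixation_duration = 0.118,
    fixation_count = 100, mean_saccade_amplitude = 0.126,
    aoi_proportions = prof$aoi_proportions, strategy = "feed_forward",
    tear_angle_mean = 6, tear_angle_sd = 1.58,
    diameter_fraction_mean = 0.576, noise_sd = 0)
  s <- generate_session(p0, view_geometry(), duration = 30, seed = 5)
  fx <- detect_fixations(filter_by_confidence(s$stream))
  tf <- truth_fixations(s)
  expect_identical(nrow(fx), nrow(tf))
  expect_equal(fx$duration, tf$end - tf$start)
  expect_true(all(fx$dispersion == 0))
  expect_equal(fx$centroid_x, tf$x)

  # default jitter (0.15 deg): still exact count closure here
  s <- generate_session(prof, view_geometry(), duration = 30, seed = 6)
  fx <- detect_fixations(filter_by_confidence(s$stream))
  expect_identical(nrow(fx), nrow(truth_fixations(s)))

  # heavy jitter (0.3 deg): counts within 2%
  p3 <- expertise_profile(
    label = "jittery", mean_fixation_duration = 0.118,
    fixation_count = 100, mean_saccade_amplitude = 0.126,
    aoi_proportions = prof$aoi_proportions, strategy = "feed_forward",
    tear_angle_mean = 6, tear_angle_sd = 1.58,
    diameter_fraction_mean = 0.576, noise_sd = 0.3)
  s <- generate_session(p3, view_geometry(), duration = 60, seed = 7)
  fx <- detect_fixations(filter_by_confidence(s$stream))
  n_true <- nrow(truth_fixations(s))
  expect_lte(abs(nrow(fx) - n_true) / n_true, 0.02)
})

test_that("blink rate of generated sessions is recovered", {
  prof <- study_profiles()$attending
  counts <- vapply(1:8, function(i) {
    s <- generate_session(prof, view_geometry(), duration = 60, seed = 100 + i)
    c(nrow(detect_blinks(s$stream)),
      sum(s$truth$kind == "blink"))
  }, numeric(2))
  # detection matches ground truth exactly
  expect_equal(counts[1, ], counts[2, ])
  # pooled rate within 3 SE (Poisson) of the profile blink rate
  total <- sum(counts[1, ])
  expected <- prof$blink_rate * 8
  expect_lte(abs(total - expected), 3 * sqrt(expected))
})
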