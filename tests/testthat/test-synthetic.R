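# Synthetic session generator: determinism, validation, moment fidelity.

test_that("identical (profile, seed) pairs reproduce identical sessions", {
  p <- study_profiles()$fellow
  g <- view_geometry()
  a <- generate_session(p, g, duration = 10, seed = 123)
  b <- generate_session(p, g, duration = 10, seed = 123)
  expect_identical(a, b)
  c_ <- generate_session(p, g, duration = 10, seed = 124)
  expect_false(identical(a$stream, c_$stream))
})

test_that("profile validation names the offending parameter", {
  ok <- study_profiles()$attending
  build <- function(...) {
    args <- utils::modifyList(
      list(label = "x", mean_fixation_duration = 0.118,
           fixation_count = 100, mean_saccade_amplitude = 0.126,
           aoi_proportions = ok$aoi_proportions, strategy = "reactive",
           tear_angle_mean = 6, tear_angle_sd = 1.58,
           diameter_fraction_mean = 0.576),
      list(...))
    do.call(expertise_profile, args)
  }
  expect_error(build(mean_fixation_duration = 0.5),
               "mean_fixation_duration")
  expect_error(build(mean_fixation_duration = NaN),
               "mean_fixation_duration")
  expect_error(build(mean_saccade_amplitude = -1),
               "mean_saccade_amplitude")
  expect_error(build(blink_rate = Inf), "blink_rate")
  expect_error(build(aoi_proportions = c(HUD = 0.5, instrument_field = 0.4,
                                         peripheral = 0.2)),
               "sum to 1")
})

test_that("sessions shorter than the fixation floor log no fixations", {
  s <- generate_session(study_profiles()$pgy2, view_geometry(),
                        duration = 0.05, seed = 1)
  expect_identical(nrow(truth_fixations(s)), 0L)
  expect_lte(max(s$stream$timestamp), 0.05)
})

test_that("generated dwell durations stay in the detectable range and hit
           the profile mean over many seeds", {
  p <- study_profiles()$attending
  g <- view_geometry()
  per_session <- vapply(1:50, function(i) {
    s <- generate_session(p, g, duration = 12, seed = 2000 + i)
    tf <- truth_fixations(s)
    expect_true(all(tf$end - tf$start >= 0.08 - 1e-9))
    expect_true(all(tf$end - tf$start <= 0.42 + 1e-9))
    mean(tf$end - tf$start)
  }, numeric(1))
  se <- sd(per_session) / sqrt(length(per_session))
  expect_lte(abs(mean(per_session) - p$mean_fixation_duration), 3 * se)
})

test_that("ground-truth AOI fractions track the profile proportions", {
  p <- study_profiles()$attending
  g <- view_geometry()
  hud <- vapply(1:40, function(i) {
    s <- generate_session(p, g, duration = 20, seed = 3000 + i)
    tf <- truth_fixations(s)
    mean(tf$aoi == "HUD")
  }, numeric(1))
  se <- sd(hud) / sqrt(length(hud))
  expect_lte(abs(mean(hud) - p$aoi_proportions[["HUD"]]), 3 * se)
})

test_that("default surfaces tile the frame with disjoint simple polygons", {
  g <- view_geometry()
  s <- generate_surfaces(g)
  expect_setequal(names(s), aoi_labels())
  areas <- vapply(s, function(z) polygon_area(z$vertices), numeric(1))
  expect_equal(sum(areas), g$width_px * g$height_px)
  # random interior points belong to exactly one polygon
  withr::with_seed(9, {
    px <- runif(500, 1, g$width_px - 1)
    py <- runif(500, 1, g$height_px - 1)
  })
  hits <- vapply(s, function(z) point_in_polygon(px, py, z$vertices),
                 logical(500))
  on_shared_edge <- abs(py - 0.55 * g$height_px) < 1e-6 |
    abs(py - 0.90 * g$height_px) < 1e-6
  expect_true(all(rowSums(hits[!on_shared_edge, , drop = FALSE]) == 1))
})

test_that("surface files round-trip exactly", {
  g <- view_geometry()
  s <- generate_surfaces(g)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_surfaces(s, path)
  s2 <- read_surfaces(path)
  expect_identical(lapply(s2, function(z) z$vertices),
                   lapply(s, function(z) z$vertices))
})

test_that("mask generation matches the analytic disk area and round-trips", {
  g <- view_geometry(width_px = 200, height_px = 160, diagonal_fov = 100)
  expect_equal(sum(is_blue(generate_mask_image(
    g, list(center = c(100, 80), radius = 0)))), 0)

  r <- 60
  m <- generate_mask_image(g, list(center = c(100, 80), radius = r))
  n_blue <- sum(is_blue(m))
  expect_lte(abs(n_blue - pi * r^2), 2 * pi * r) # rasterization tolerance

  expect_error(generate_mask_image(g, list(center = c(10, 10), radius = 60)),
               "inside the frame")

  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, path)
  m2 <- read_mask_png(path)
  expect_identical(is_blue(m2), is_blue(m))
})

test_that("tear annotations recover the drawn angle and fraction", {
  base <- study_profiles()$attending
  exact <- expertise_profile(
    label = "exact45", mean_fixation_duration = 0.118,
    fixation_count = 100, mean_saccade_amplitude = 0.126,
    aoi_proportions = base$aoi_proportions, strategy = "feed_forward",
    tear_angle_mean = 45, tear_angle_sd = 0,
    diameter_fraction_mean = 0.5, diameter_fraction_sd = 0)
  a <- generate_tear_annotation(exact, seed = 3)
  expect_equal(tear_angle(a), 45, tolerance = 1e-8)
  expect_equal(diameter_fraction(a), 0.5, tolerance = 1e-3)

  expect_identical(generate_tear_annotation(base, seed = 11),
                   generate_tear_annotation(base, seed = 11))

  # experts initiate near the wound, novices far from it
  near <- vapply(1:20, function(i) initiation_distance(
    generate_tear_annotation(study_profiles()$attending, seed = i)),
    numeric(1))
  far <- vapply(1:20, function(i) initiation_distance(
    generate_tear_annotation(study_profiles()$pgy2, seed = i)),
    numeric(1))
  expect_lt(mean(near), mean(far))
})

test_that("cohorts derive distinct reproducible seeds per session", {
  profs <- study_profiles()
  co <- generate_cohort(profs, n_per_group = 5, base_seed = 77,
                        duration = 1)
  expect_identical(length(co$sessions), 25L)
  expect_identical(nrow(co$manifest), 25L)
  expect_identical(anyDuplicated(co$manifest$seed), 0L)

  co2 <- generate_cohort(profs, n_per_group = 5, base_seed = 77,
                         duration = 1)
  expect_identical(co$manifest, co2$manifest)

  co1 <- generate_cohort(profs[c("pgy2", "attending")], n_per_group = 1,
                         base_seed = 1, duration = 1)
  expect_identical(length(co1$sessions), 2L)

  dup <- profs[c("pgy2", "pgy2")]
  expect_error(generate_cohort(dup, 2, 1, duration = 1), "distinct")
})
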