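# Marker painting, coverage quantification and heatmaps.

small_geom <- function() view_geometry(width_px = 240, height_px = 180,
                                       diagonal_fov = 100)

test_that("painting no fixations leaves the mask untouched", {
  g <- small_geom()
  m <- generate_mask_image(g, list(center = c(120, 90), radius = 60))
  out <- paint_markers(m, fake_fixations(numeric(0), numeric(0),
                                         numeric(0), numeric(0)),
                       5, g)
  expect_identical(unclass(out), unclass(m))
})

test_that("a single interior marker paints the analytic disk area", {
  g <- small_geom()
  m <- generate_mask_image(g, list(center = c(120, 90), radius = 0))
  fx <- fake_fixations(0, 0.2, cx = 120 * g$deg_per_px,
                       cy = 90 * g$deg_per_px)
  out <- paint_markers(m, fx, marker_size = 5, geometry = g)
  painted <- sum(out[, , 1] == 1 & out[, , 2] == 0 & out[, , 3] == 0)
  r_px <- 2.5 / g$deg_per_px
  expect_lte(abs(painted - pi * r_px^2), 2 * pi * r_px + 4)
  # radius interpretation doubles the linear size
  out_r <- paint_markers(m, fx, marker_size = 5, geometry = g,
                         size_is = "radius")
  painted_r <- sum(out_r[, , 2] == 0)
  expect_gt(painted_r, 3 * painted)
})

test_that("painting is idempotent and coincident fixations add nothing", {
  g <- small_geom()
  m <- generate_mask_image(g, list(center = c(120, 90), radius = 60))
  fx1 <- fake_fixations(0, 0.2, cx = 110 * g$deg_per_px,
                        cy = 90 * g$deg_per_px)
  fx2 <- fake_fixations(c(0, 0.3), c(0.2, 0.5),
                        cx = rep(110 * g$deg_per_px, 2),
                        cy = rep(90 * g$deg_per_px, 2))
  once <- paint_markers(m, fx1, 5, g)
  twice <- paint_markers(m, fx2, 5, g)
  again <- paint_markers(once, fx1, 5, g)
  expect_identical(unclass(twice), unclass(once))
  expect_identical(unclass(again), unclass(once))
})

test_that("coverage counts blue pixels newly covered, on either
           denominator", {
  g <- small_geom()
  base <- generate_mask_image(g, list(center = c(120, 90), radius = 60))

  expect_equal(coverage_fraction(base, base)$covered_fraction, 0)

  allred <- base
  allred[, , 1] <- 1; allred[, , 2] <- 0; allred[, , 3] <- 0
  full <- coverage_fraction(base, allred, denominator = "blue_region")
  expect_equal(full$covered_fraction, 1)
  frame <- coverage_fraction(base, allred)
  expect_equal(frame$covered_fraction,
               sum(is_blue(base)) / (240 * 180))

  other <- generate_mask_image(view_geometry(100, 100, 90),
                               list(center = c(50, 50), radius = 10))
  expect_error(coverage_fraction(base, other), "dimensions")
})

test_that("coverage is monotone, sub-additive and bounded", {
  g <- small_geom()
  base <- generate_mask_image(g, list(center = c(120, 90), radius = 60))
  withr::with_seed(31, {
    cx <- runif(8, 80, 160) * g$deg_per_px
    cy <- runif(8, 60, 120) * g$deg_per_px
  })
  fx <- fake_fixations(seq(0, by = 0.3, length.out = 8),
                       seq(0.2, by = 0.3, length.out = 8), cx, cy)
  fracs <- vapply(1:8, function(k) {
    coverage_fraction(base, paint_markers(base, fx[1:k, ], 5, g)
                      )$covered_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_true(all(fracs >= 0 & fracs <= 1))

  # sub-additivity of split marker sets
  a <- coverage_fraction(base, paint_markers(base, fx[1:4, ], 5, g))
  b <- coverage_fraction(base, paint_markers(base, fx[5:8, ], 5, g))
  expect_lte(fracs[8], a$covered_fraction + b$covered_fraction + 1e-12)

  # zero iff no blue pixel is overpainted
  off <- fake_fixations(0, 0.2, cx = 10 * g$deg_per_px,
                        cy = 10 * g$deg_per_px)
  expect_equal(coverage_fraction(base, paint_markers(base, off, 2, g)
                                 )$covered_fraction, 0)
})

test_that("heatmaps peak at fixations and conserve kernel mass", {
  g <- small_geom()
  fx <- fake_fixations(0, 0.2, cx = 120 * g$deg_per_px,
                       cy = 90 * g$deg_per_px)
  grid <- fixation_heatmap(fx, g, kernel_sd = 1)
  peak <- which(grid == max(grid), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(90, 120), tolerance = 1)

  # interior kernels integrate to ~1 each
  withr::with_seed(8, {
    cx <- runif(5, 60, 180) * g$deg_per_px
    cy <- runif(5, 45, 135) * g$deg_per_px
  })
  fx5 <- fake_fixations(seq(0, by = 0.3, length.out = 5),
                        seq(0.2, by = 0.3, length.out = 5), cx, cy)
  grid5 <- fixation_heatmap(fx5, g, kernel_sd = 0.8)
  expect_equal(sum(grid5), 5, tolerance = 0.01)

  # two equal clusters -> two equal-height modes
  fx2 <- fake_fixations(c(0, 0.3), c(0.2, 0.5),
                        cx = c(80, 160) * g$deg_per_px,
                        cy = c(90, 90) * g$deg_per_px)
  g2 <- fixation_heatmap(fx2, g, kernel_sd = 0.5)
  expect_equal(g2[90, 80], g2[90, 160], tolerance = 1e-6)
  expect_equal(max(g2), g2[90, 80], tolerance = 1e-6)

  # empty input -> zero grid; normalization caps at 1
  expect_true(all(fixation_heatmap(fx5[0, ], g, 1) == 0))
  expect_equal(max(fixation_heatmap(fx5, g, 0.8, normalize = TRUE)), 1)
})
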