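# Ring photometry: integrated brightness, rim-to-rim diameter, counting.

test_that("uniform disc brightness is a times n with zero background", {
  img <- matrix(0, 41, 41)
  img[16:26, 16:26] <- 2.5                 # 11x11 "disc", a = 2.5
  m <- ring_brightness(img, c(20, 20), box_halfwidth_px = 7)
  expect_equal(m$integrated_brightness, 2.5 * 121, tolerance = 1e-12)
})

test_that("generator ring brightness is recovered within Poisson error", {
  rf <- gen_ring_field(1, brightness_mean = 4e4, brightness_cv = 0,
                       field_um = 8, background_photons = 3, seed = 5)
  img <- get_frame(rf$stack)
  m <- ring_brightness(img, c(rf$truth$x_px[1], rf$truth$y_px[1]),
                       box_halfwidth_px = 8)
  # Poisson error of the integrated counts (signal + background in the box)
  tol <- 4 * sqrt(rf$truth$brightness[1] + 3 * (2 * 8 + 1)^2)
  expect_lt(abs(m$integrated_brightness - rf$truth$brightness[1]), tol)

  # noiseless pixel-sum oracle
  rf0 <- gen_ring_field(1, brightness_mean = 4e4, brightness_cv = 0,
                        field_um = 8, background_photons = 0, noise = FALSE,
                        seed = 5)
  m0 <- ring_brightness(get_frame(rf0$stack),
                        c(rf0$truth$x_px[1], rf0$truth$y_px[1]),
                        box_halfwidth_px = 8)
  expect_equal(m0$integrated_brightness, rf0$truth$brightness[1],
               tolerance = 1e-3)
})

test_that("brightness is additive over disjoint rings in one box", {
  img <- matrix(0, 61, 61)
  img[20:24, 20:24] <- 3
  img[40:44, 40:44] <- 7
  both <- ring_brightness(img, c(30, 30), box_halfwidth_px = 20)
  one <- ring_brightness(img * (row(img) < 32), c(30, 30),
                         box_halfwidth_px = 20)
  two <- ring_brightness(img * (row(img) >= 32), c(30, 30),
                         box_halfwidth_px = 20)
  expect_equal(both$integrated_brightness,
               one$integrated_brightness + two$integrated_brightness,
               tolerance = 1e-12)
})

test_that("overlapping detections are flagged and excluded from reference", {
  img <- matrix(1, 80, 80)
  det <- data.frame(x_px = c(20, 26, 60), y_px = c(20, 20, 60))
  res <- measure_ring_field(img, det, box_halfwidth_px = 6)
  expect_identical(res$overlapping, c(TRUE, TRUE, FALSE))
})

test_that("ring diameter comes from rim peak spacing with subpixel refinement", {
  # constructed rims exactly 0.44 um apart at 0.02 um sampling
  x <- seq(0, 1.2, by = 0.02)
  prof <- exp(-(x - 0.38)^2 / (2 * 0.05^2)) +
    exp(-(x - 0.82)^2 / (2 * 0.05^2))
  r <- ring_diameter(prof, spacing_um = 0.02)
  expect_true(r$resolved)
  expect_equal(r$diameter_um, 0.44, tolerance = 0.005)

  # blurred annulus of true diameter 0.8 um: peak-to-peak within 1 px
  rf <- gen_ring_field(1, diameter_um = 0.8, brightness_mean = 8e4,
                       brightness_cv = 0, field_um = 8, seed = 7)
  img <- get_frame(rf$stack)
  row_at <- round(rf$truth$y_px[1]) + 1
  r2 <- ring_diameter(img[row_at, ], spacing_um = rf$stack$pixel_size_um)
  expect_lt(abs(r2$diameter_um - 0.8), rf$stack$pixel_size_um)

  # invariance under intensity scaling
  r3 <- ring_diameter(7 * prof, spacing_um = 0.02)
  expect_equal(r3$diameter_um, r$diameter_um, tolerance = 1e-12)

  expect_false(ring_diameter(exp(-(x - 0.5)^2 / 0.01),
                             spacing_um = 0.02)$resolved)
})

test_that("the two mutant fixtures reproduce distinct diameter regimes", {
  ds <- vapply(c(0.44, 0.89), function(dd) {
    rf <- gen_ring_field(1, diameter_um = dd, brightness_mean = 8e4,
                         brightness_cv = 0, field_um = 8,
                         psf_sigma_um = 0.1, seed = 3)
    img <- get_frame(rf$stack)
    ring_diameter(img[round(rf$truth$y_px[1]) + 1, ],
                  spacing_um = rf$stack$pixel_size_um)$diameter_um
  }, numeric(1))
  expect_lt(abs(ds[1] - 0.44), 0.11)
  expect_lt(abs(ds[2] - 0.89), 0.11)
  expect_gt(ds[2], 1.5 * ds[1])
})

test_that("ring counting divides brightness by the single-ring reference", {
  cnt <- count_rings_on_tube(5 * 1200, 1200, 5, n_reference_rings = 20)
  expect_equal(cnt$n_rings, 5)
  expect_equal(cnt$rings_per_um, 1)
  expect_true(cnt$reliable)
  expect_false(count_rings_on_tube(100, 50, 2,
                                   n_reference_rings = 4)$reliable)
  expect_error(count_rings_on_tube(100, 0, 2))
})

test_that("a tube assembled from k generator rings counts back to k", {
  k <- 6
  rf <- gen_ring_field(k, diameter_um = 0.44, brightness_mean = 3e4,
                       brightness_cv = 0.15, field_um = 25, seed = 21)
  img <- get_frame(rf$stack)
  meas <- measure_ring_field(img, rf$truth, box_halfwidth_px = 7)
  ref <- ring_brightness_reference(meas)
  tube_brightness <- sum(meas$integrated_brightness)
  cnt <- count_rings_on_tube(tube_brightness, ref$per_ring_brightness, k,
                             n_reference_rings = ref$n_used)
  # median reference vs mean assembly: allow the brightness CV spread
  expect_lt(abs(cnt$n_rings - k) / k, 0.2)
})

test_that("blob detection finds isolated generator rings", {
  rf <- gen_ring_field(5, diameter_um = 0.6, brightness_mean = 6e4,
                       brightness_cv = 0, field_um = 20, seed = 13)
  img <- get_frame(rf$stack)
  det <- detect_rings(img, expected_radius_px = 0.3 / 0.11)
  expect_gte(nrow(det), 5)
  # every true ring has a detection within 2 px
  for (i in seq_len(5)) {
    d <- sqrt((det$x_px - rf$truth$x_px[i])^2 +
                (det$y_px - rf$truth$y_px[i])^2)
    expect_lt(min(d), 2)
  }
})
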