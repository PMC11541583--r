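test_that("grey conversion averages channels with half-up rounding", {
  g <- image_frame(matrix(7, 8, 8), 8L)
  expect_identical(to_grey(g)$pixels, g$pixels)

  px <- array(5, c(8, 8, 3))
  fr <- image_frame(px, 8L)
  expect_true(all(to_grey(fr)$pixels == 5))

  set.seed(21)
  px <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  fr <- image_frame(px, 8L)
  oracle <- floor((px[, , 1] + px[, , 2] + px[, , 3]) / 3 + 0.5)
  expect_identical(to_grey(fr)$pixels, oracle)
})

test_that("rolling-ball subtraction removes smooth background, keeps peaks", {
  const <- image_frame(matrix(120, 64, 64), 8L, pixel_size = 1)
  expect_true(all(subtract_background(const, 10)$pixels == 0))

  ramp <- matrix(rep(seq(0, 200, length.out = 128), each = 128), 128)
  fr <- image_frame(ramp, 8L, pixel_size = 1)
  res <- subtract_background(fr, 15)$pixels
  expect_lt(max(res), 0.05 * 200)

  spot <- ramp
  spot[60:68, 60:68] <- spot[60:68, 60:68] + 50
  res2 <- subtract_background(image_frame(spot, 8L, 1), 15)$pixels
  expect_gt(max(res2[60:68, 60:68]), 0.9 * 50)
  expect_lt(max(res2[60:68, 60:68]), 1.1 * 50)

  expect_error(subtract_background(const, 0.2), class = "validation_error")
})

test_that("foreground detection matches pixelwise oracle and handles Otsu", {
  set.seed(3)
  px <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32)
  fr <- image_frame(px, 8L)
  m <- detect_foreground(fr, method = 120)
  expect_identical(as.vector(m), as.vector(px > 120))
  expect_equal(attr(m, "threshold"), 120)

  zero <- image_frame(matrix(0, 16, 16), 8L)
  expect_false(any(detect_foreground(zero, method = 0)))
  expect_error(detect_foreground(zero, method = "otsu"),
               class = "degenerate_histogram_error")

  # cross-check our Otsu against EBImage's on a bimodal image: both must
  # achieve the optimal between-class variance (the optimum can be a
  # plateau; ours takes its lowest point by design)
  set.seed(9)
  px <- matrix(c(rnorm(500, 60, 10), rnorm(524, 190, 12)), 32)
  px <- pmin(pmax(round(px), 0), 255)
  ours <- threshold_otsu(px, levels = 256)
  ref <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1),
                       levels = 256) * 255
  between_var <- function(v, t) {
    w0 <- mean(v <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(v[v <= t]) - mean(v[v > t]))^2
  }
  v <- as.vector(px)
  expect_gte(between_var(v, ours), between_var(v, ref) - 1e-9)
  expect_lte(ours, ref + 255 / 256)
})

test_that("Otsu recovers the planted foreground of a noise-free phantom", {
  ph <- make_stellate(noise_sd = 0, seed = 8)
  an <- analyze_stellate(ph$image)
  planted <- ph$truth$objects$core_mask | ph$truth$objects$invader_mask
  expect_false(any(outside_boundary_band(an$zones$foreground, planted)))
})

test_that("density map is a normalised local foreground fraction", {
  full <- matrix(TRUE, 64, 64)
  expect_equal(max(abs(density_map(full, 5, 1) - 1)), 0, tolerance = 1e-6)
  empty <- matrix(FALSE, 64, 64)
  expect_equal(max(density_map(empty, 5, 1)), 0)
  half <- matrix(FALSE, 64, 64); half[, 1:32] <- TRUE
  d <- density_map(half, 4, 1)
  # kernel symmetry puts the half-level on the set/unset boundary
  expect_equal(mean(d[, 32:33]), 0.5, tolerance = 0.01)
})

test_that("zone split partitions the foreground exactly", {
  expect_error(split_zones(matrix(TRUE, 4, 4), matrix(1, 4, 4),
                           d_hi = 0.3, d_lo = 0.5),
               class = "validation_error")
  expect_error(split_zones(matrix(TRUE, 8, 8), matrix(0.1, 8, 8)),
               class = "no_spheroid_error")

  for (seed in 1:4) {
    set.seed(seed)
    fg <- matrix(runif(64 * 64) < 0.4, 64)
    fg[20:44, 20:44] <- TRUE
    dens <- density_map(fg, 5, 1)
    z <- split_zones(fg, dens)
    expect_false(any(z$inner_core & z$outer_core))
    expect_false(any(z$inner_core & z$periphery))
    expect_false(any(z$outer_core & z$periphery))
    expect_identical(z$inner_core | z$outer_core | z$periphery,
                     unname(z$foreground))
  }
})

test_that("uniform disc phantom has essentially no periphery", {
  ph <- make_stellate(n_strands = 0, seed = 13)
  an <- analyze_stellate(ph$image)
  fg_area <- sum(an$zones$foreground) * ph$image$pixel_size^2
  expect_lt(an$metrics$peripheral_area / fg_area, 0.02)
})

test_that("stellate phantom areas are recovered within tolerance", {
  ph <- make_stellate(core_radius = 150, n_strands = 12, seed = 17)
  an <- analyze_stellate(ph$image)
  tr <- ph$truth$objects
  core_meas <- an$metrics$inner_area + an$metrics$outer_area
  expect_lt(abs(core_meas / tr$core_area_um2 - 1), 0.10)
  expect_lt(abs(an$metrics$peripheral_area / tr$invader_area_um2 - 1), 0.15)
})

test_that("circularity behaves like an isoperimetric quotient", {
  disc <- raster_disc()
  sq <- raster_square()
  star <- raster_star()
  c_disc <- region_metrics(disc, 1)$circularity
  c_sq <- region_metrics(sq, 1)$circularity
  c_star <- region_metrics(star, 1)$circularity
  expect_gte(c_disc, 0.98)
  expect_equal(c_sq, pi / 4, tolerance = 0.02 / (pi / 4))
  # 4-armed star is far less compact than a disc of the same area
  same_area_disc <- raster_disc(r = sqrt(sum(star) / pi))
  expect_lt(c_star, region_metrics(same_area_disc, 1)$circularity)

  zones <- list(inner_core = disc, outer_core = matrix(FALSE, 256, 256),
                periphery = matrix(FALSE, 256, 256))
  m1 <- stellate_metrics(zones, pixel_size = 1)
  m2 <- stellate_metrics(zones, pixel_size = 2)
  expect_equal(m2$inner_area, 4 * m1$inner_area)
  expect_equal(m2$inner_circularity, m1$inner_circularity, tolerance = 1e-9)
  zones$inner_core <- matrix(FALSE, 4, 4)
  expect_error(stellate_metrics(zones, 1),
               class = "undefined_circularity_error")
})

test_that("adding invader strands raises periphery, not inner circularity", {
  periph <- numeric(0); circ <- numeric(0)
  for (ns in c(0, 6, 12)) {
    ph <- make_stellate(n_strands = ns, seed = 23)
    m <- analyze_stellate(ph$image)$metrics
    periph <- c(periph, m$peripheral_area)
    circ <- c(circ, m$inner_circularity)
  }
  expect_true(all(diff(periph) >= 0))
  expect_true(all(diff(circ) <= 0.005))
})
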