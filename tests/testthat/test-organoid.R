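blank_frame <- function(n = 64) image_frame(matrix(0, n, n), 16L, 1)

test_that("blank channels yield empty detections", {
  expect_equal(nrow(detect_dead_cells(blank_frame())$points), 0)
  expect_false(any(detect_dead_cells(blank_frame())$mask))
  expect_equal(nrow(detect_live_cells(blank_frame())$points), 0)
  expect_equal(max(detect_spheroids(blank_frame(),
                                    intensity_thresh = 10,
                                    thresh_type = "absolute")), 0)
})

test_that("dual-engine dead-cell detection recovers planted dots exactly", {
  ph <- make_organoid_field(noise_sd = 0, seed = 31)
  det <- detect_dead_cells(ph$orange)
  tr <- ph$truth$objects
  expect_equal(nrow(det$points), tr$total_dead)
  # every detection sits within half a dot diameter of a planted dot
  planted <- do.call(rbind, lapply(tr$spheroids, function(s) s$dead))
  for (i in seq_len(nrow(det$points))) {
    d <- sqrt((planted$x_um - det$points$x_um[i])^2 +
                (planted$y_um - det$points$y_um[i])^2)
    expect_lt(min(d), 4)
  }
  # union property: merged mask contains the plain threshold mask
  thr_mask <- ph$orange$pixels > 0.5 * max(ph$orange$pixels)
  expect_true(all(det$mask[thr_mask]))
})

test_that("live detection count is non-increasing in the threshold", {
  ph <- make_organoid_field(noise_sd = 0, seed = 37)
  n_lo <- nrow(detect_live_cells(ph$green, intensity_thresh = 0.5)$points)
  n_mid <- nrow(detect_live_cells(ph$green, intensity_thresh = 0.6)$points)
  n_hi <- nrow(detect_live_cells(ph$green, intensity_thresh = 0.8)$points)
  expect_gte(n_lo, n_mid)
  expect_gte(n_mid, n_hi)
  expect_equal(n_mid, ph$truth$objects$total_live)
})

test_that("spheroid detection applies the double threshold on intensity and area", {
  px <- matrix(0, 128, 128)
  big_r <- c(20, 20, 90, 90, 55); big_c <- c(20, 90, 20, 90, 55)
  for (i in 1:5)
    px[outer((1:128) - big_r[i], (1:128) - big_c[i],
             function(a, b) a^2 + b^2) <= 10^2] <- 200
  small_r <- c(5, 120, 120); small_c <- c(64, 5, 120)
  for (i in 1:3)
    px[outer((1:128) - small_r[i], (1:128) - small_c[i],
             function(a, b) a^2 + b^2) <= 2^2] <- 200
  fr <- image_frame(px, 8L, 1)
  lab <- detect_spheroids(fr, intensity_thresh = 100,
                          thresh_type = "absolute", min_area = 100)
  expect_equal(max(lab), 5)
  lab_all <- detect_spheroids(fr, intensity_thresh = 100,
                              thresh_type = "absolute", min_area = 0)
  expect_equal(max(lab_all), 8)
  expect_equal(sort(unique(as.vector(lab))), 0:5)

  flat <- image_frame(matrix(50, 32, 32), 8L, 1)
  expect_equal(max(detect_spheroids(flat, intensity_thresh = 100,
                                    thresh_type = "absolute",
                                    min_area = 1)), 0)
  # relative threshold makes the count scale-invariant
  fr3 <- image_frame(px * 1.2, 16L, 1)
  expect_equal(max(detect_spheroids(fr3, intensity_thresh = 0.5,
                                    min_area = 100)),
               max(detect_spheroids(fr, intensity_thresh = 0.5,
                                    min_area = 100)))
})

test_that("per-spheroid statistics recover planted counts", {
  ph <- make_organoid_field(noise_sd = 0, seed = 41)
  live <- detect_live_cells(ph$green)
  dead <- detect_dead_cells(ph$orange)
  sph <- detect_spheroids(ph$green)
  st <- spheroid_stats(sph, live, dead, ph$green, ph$orange, 1)
  tr <- ph$truth$objects
  expect_equal(st$summary$spheroid_count, tr$n_spheroids)
  # match truth spheroids to labels through their centres
  lab_at <- vapply(tr$spheroids, function(s)
    sph[round(s$y_um) + 1, round(s$x_um) + 1], integer(1))
  expect_true(all(lab_at > 0))
  expect_equal(st$records$dead_count[lab_at],
               vapply(tr$spheroids, function(s) nrow(s$dead), integer(1)))
  expect_equal(st$records$live_count[lab_at],
               vapply(tr$spheroids, function(s) nrow(s$live), integer(1)))
  expect_lte(sum(st$records$live_count), nrow(live$points))
  expect_true(all(st$records$circularity > 0.9))

  empty <- spheroid_stats(matrix(0L, 64, 64),
                          detect_live_cells(blank_frame()),
                          detect_dead_cells(blank_frame()),
                          blank_frame(), blank_frame(), 1)
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$summary$spheroid_count, 0)
  expect_error(spheroid_stats(matrix(0L, 4, 4),
                              detect_live_cells(blank_frame()),
                              detect_dead_cells(blank_frame()),
                              blank_frame(), blank_frame(), 1),
               class = "validation_error")
})

test_that("maximum projection equals the per-pixel max oracle", {
  f1 <- image_frame(matrix(0, 16, 16), 8L)
  st1 <- image_stack(list(f1), axis = "z")
  expect_identical(max_projection(st1)$pixels, f1$pixels)

  a <- matrix(0, 16, 16); a[4, 4] <- 200
  b <- matrix(0, 16, 16); b[12, 12] <- 150
  st2 <- image_stack(list(image_frame(a, 8L), image_frame(b, 8L)), axis = "z")
  mp <- max_projection(st2)$pixels
  expect_equal(mp[4, 4], 200)
  expect_equal(mp[12, 12], 150)

  set.seed(5)
  planes <- lapply(1:3, function(i)
    matrix(sample(0:255, 64, replace = TRUE), 8))
  st3 <- image_stack(lapply(planes, image_frame, bit_depth = 8L), axis = "z")
  expect_identical(max_projection(st3)$pixels, pmax(planes[[1]], planes[[2]],
                                                    planes[[3]]))
  stt <- image_stack(list(f1), axis = "t")
  expect_error(max_projection(stt), class = "validation_error")
})
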