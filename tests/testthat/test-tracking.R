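test_that("spot detection finds planted spots and honours the window", {
  blank <- image_frame(matrix(0, 64, 64), 8L, 1)
  expect_equal(nrow(detect_spots(blank)), 0)

  ph <- make_track_movie(n_particles = 6, speed = 5, n_frames = 5,
                         dropout_frames = lapply(1:6, function(i) integer(0)),
                         seed = 11)
  sp <- detect_spots(ph$movie$frames[[1]])
  expect_equal(nrow(sp), 6)
  truth <- ph$truth$objects$positions[, 1, ]
  for (i in seq_len(6)) {
    d <- sqrt((sp$x_um - truth[i, 1])^2 + (sp$y_um - truth[i, 2])^2)
    expect_lt(min(d), 1)
  }
  # a spot brighter than the window's upper bound is excluded
  bright <- ph$movie$frames[[1]]$pixels
  bright[32, 32] <- 255
  fr <- image_frame(bright, 8L, 1)
  sp2 <- detect_spots(fr, intensity_window = c(30, 230))
  d <- sqrt((sp2$x_um - 31)^2 + (sp2$y_um - 31)^2)
  expect_true(!nrow(sp2) || min(d) > 3)
  expect_error(detect_spots(blank, diameter = 1),
               class = "validation_error")
  expect_error(detect_spots(blank, intensity_window = c(5, 5)),
               class = "validation_error")
})

test_that("frame-pair assignment equals exhaustive minimum-cost matching", {
  for (seed in 1:8) {
    set.seed(seed)
    na_ <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- data.frame(x_um = runif(na_, 0, 60), y_um = runif(na_, 0, 60))
    b <- data.frame(x_um = runif(nb, 0, 60), y_um = runif(nb, 0, 60))
    idx <- cytomorph:::match_frame_pair(a, b, max_dist = 25)
    got <- matching_cost(a, b, idx)
    want <- brute_force_match(a, b, max_dist = 25)
    expect_equal(got$n, want$n)
    expect_equal(got$cost, want$cost, tolerance = 1e-9)
  }
})

test_that("linking obeys the gap contract and conserves detections", {
  ph <- make_track_movie(n_particles = 1, speed = 5, n_frames = 10,
                         dropout_frames = list(4L), seed = 19)
  spots <- detect_spots_stack(ph$movie)
  t1 <- link_tracks(spots, max_dist = 20, max_gap = 1)
  t0 <- link_tracks(spots, max_dist = 20, max_gap = 0)
  expect_equal(length(unique(t1$track_id)), 1)
  expect_equal(length(unique(t0$track_id)), 2)

  # no dropout: one track covering every frame
  ph2 <- make_track_movie(n_particles = 1, speed = 5, n_frames = 12,
                          dropout_frames = list(integer(0)), seed = 23)
  tr <- link_tracks(detect_spots_stack(ph2$movie), 20, 5)
  expect_equal(unique(tr$track_id), 1L)
  expect_equal(tr$frame, 1:12)

  # conservation: every detection appears exactly once
  ph3 <- make_track_movie(n_particles = 5, n_frames = 15,
                          dropout_frames = 0.1, seed = 29)
  spots3 <- detect_spots_stack(ph3$movie)
  tr3 <- link_tracks(spots3, 20, 5)
  expect_equal(nrow(tr3), sum(vapply(spots3, nrow, integer(1))))
  expect_false(any(duplicated(tr3[, c("frame", "x_um", "y_um")])))
})

test_that("track speed is displacement over elapsed time", {
  tr <- data.frame(frame = 1:5, x_um = (0:4) * 5, y_um = 0)
  expect_equal(track_speed(tr, frame_interval = 20), 0.25)
  still <- data.frame(frame = 1:4, x_um = 3, y_um = 7)
  expect_equal(track_speed(still, 20), 0)
  expect_error(track_speed(data.frame(frame = 1, x_um = 0, y_um = 0), 20),
               class = "undefined_speed_error")

  ph <- make_track_movie(n_particles = 4, speed = 6, n_frames = 20,
                         dropout_frames = 0.1, seed = 31)
  tracks <- link_tracks(detect_spots_stack(ph$movie), 20, 5)
  summ <- summarize_tracks(tracks, frame_interval = 20)
  expect_equal(nrow(summ), 4)
  rel_err <- abs(summ$mean_speed_um_per_min - 6 / 20) / (6 / 20)
  expect_lt(median(rel_err), 0.02)
})

test_that("surface morphometry matches closed forms for ball and cube", {
  ball <- voxel_ball(20)
  sb <- surface_morphometry(ball, 1)
  expect_equal(sb$volume_um3, sum(ball))
  expect_gte(sb$sphericity, 0.95)
  expect_lte(sb$sphericity, 1)

  cube <- voxel_cube(40)
  sc <- surface_morphometry(cube, 1)
  expect_equal(sc$volume_um3, 40^3)
  expect_equal(sc$sphericity, (pi / 6)^(1 / 3), tolerance = 0.03 / 0.8)

  # psi is scale-invariant (voxel size only rescales V and A consistently)
  sc2 <- surface_morphometry(cube, 2.5)
  expect_equal(sc2$sphericity, sc$sphericity, tolerance = 1e-9)
  expect_equal(sc2$volume_um3, sc$volume_um3 * 2.5^3)
  expect_error(surface_morphometry(array(FALSE, c(4, 4, 4)), 1),
               class = "validation_error")
})

test_that("confluence area counts supra-threshold pixels", {
  blank <- image_frame(matrix(0, 32, 32), 8L, 1.5)
  expect_equal(confluence_area(blank, 10), 0)
  half <- matrix(0, 32, 32); half[, 1:16] <- 200
  fr <- image_frame(half, 8L, 1.5)
  expect_equal(confluence_area(fr, 100), 16 * 32 * 1.5^2)

  ph <- make_organoid_field(n_spheroids = 6, noise_sd = 0, seed = 43)
  planted <- sum(vapply(ph$truth$objects$spheroids, `[[`, numeric(1),
                        "area_um2"))
  meas <- confluence_area(ph$green, 0.1 * max(ph$green$pixels))
  perim_band <- sum(vapply(ph$truth$objects$spheroids, function(s)
    2 * pi * s$r_um + 10, numeric(1)))
  expect_lt(abs(meas - planted), perim_band)
})
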