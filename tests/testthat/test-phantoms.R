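test_that("phantom generators are deterministic under a fixed seed", {
  a <- make_stellate(seed = 7); b <- make_stellate(seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$objects$core_area_um2, b$truth$objects$core_area_um2)

  a <- make_organoid_field(seed = 7); b <- make_organoid_field(seed = 7)
  expect_identical(a$green$pixels, b$green$pixels)
  expect_identical(a$orange$pixels, b$orange$pixels)

  a <- make_tube_lattice(jitter = 5, seed = 7)
  b <- make_tube_lattice(jitter = 5, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)

  a <- make_track_movie(seed = 7, dropout_frames = 0.1)
  b <- make_track_movie(seed = 7, dropout_frames = 0.1)
  expect_identical(a$truth$objects$positions, b$truth$objects$positions)
  expect_identical(a$movie$frames[[5]]$pixels, b$movie$frames[[5]]$pixels)
})

test_that("stellate phantom truth matches its geometry", {
  ph <- make_stellate(n_strands = 0, noise_sd = 0, seed = 1)
  expect_equal(ph$truth$objects$invader_area_um2, 0)

  ph <- make_stellate(core_radius = 150, seed = 2, pixel_size = 2)
  tr <- ph$truth$objects
  # rasterised core area within one pixel-perimeter band of pi r^2
  band <- 2 * pi * 150 * 2 + 4 * 2^2
  expect_lt(abs(tr$core_area_um2 - pi * 150^2), band)
  # geometry exceeding the image is rejected
  expect_error(make_stellate(core_radius = 300, strand_length = 400),
               class = "validation_error")
})

test_that("thresholding a noise-free stellate phantom recovers planted masks", {
  ph <- make_stellate(noise_sd = 0, illum_gradient = 0, seed = 5)
  px <- ph$image$pixels
  mx <- 2^ph$image$bit_depth - 1
  # brightfield: objects darker; half-way between object and background
  fg <- (mx - px) > (mx - 0.60 * mx)
  planted <- ph$truth$objects$core_mask | ph$truth$objects$invader_mask
  expect_false(any(outside_boundary_band(fg, planted)))
})

test_that("organoid phantom bookkeeping is exact by construction", {
  ph <- make_organoid_field(n_spheroids = 0, noise_sd = 0, seed = 1)
  expect_equal(max(ph$green$pixels), 0)
  expect_equal(max(ph$orange$pixels), 0)
  expect_length(ph$truth$objects$spheroids, 0)

  ph <- make_organoid_field(n_spheroids = 12, seed = 3)
  tr <- ph$truth$objects
  expect_length(tr$spheroids, 12)
  expect_equal(tr$total_dead,
               sum(vapply(tr$spheroids, function(s) nrow(s$dead), numeric(1))))
  expect_equal(tr$total_live,
               sum(vapply(tr$spheroids, function(s) nrow(s$live), numeric(1))))
  # all planted points lie inside their spheroid
  for (s in tr$spheroids) {
    if (nrow(s$live))
      expect_true(all(sqrt((s$live$x_um - s$x_um)^2 +
                             (s$live$y_um - s$y_um)^2) <= s$r_um))
  }
  expect_error(
    make_organoid_field(n_spheroids = 80, min_separation = 100, seed = 1),
    class = "packing_error")
})

test_that("tube lattice truth encodes the generating graph", {
  ph <- make_tube_lattice(rows = 2, cols = 3, edge_len = 50, tube_width = 7,
                          jitter = 0, seed = 1)
  tr <- ph$truth$objects
  expect_equal(tr$n_meshes, 6)
  # 12 grid nodes minus the 4 degree-2 corners
  expect_equal(tr$n_junctions, 8)
  analytic <- (2 + 1) * 3 * 50 + (3 + 1) * 2 * 50
  expect_equal(tr$total_edge_len_um, analytic)

  phj <- make_tube_lattice(rows = 2, cols = 3, edge_len = 50, tube_width = 7,
                           jitter = 4, seed = 2)
  nedge <- nrow(phj$truth$objects$edges)
  expect_lt(abs(phj$truth$objects$total_edge_len_um - analytic),
            nedge * 2 * sqrt(2) * 4)
  expect_error(make_tube_lattice(tube_width = 120, edge_len = 100),
               class = "validation_error")
})

test_that("track movie plants exact trajectories and dropouts", {
  ph <- make_track_movie(n_particles = 1, speed = 5, n_frames = 10,
                         dropout_frames = list(integer(0)), seed = 1)
  pos <- ph$truth$objects$positions
  steps <- sqrt(diff(pos[1, , 1])^2 + diff(pos[1, , 2])^2)
  expect_equal(steps, rep(5, 9))

  phd <- make_track_movie(n_particles = 1, speed = 5, n_frames = 6,
                          dropout_frames = list(3L), seed = 2)
  p <- phd$truth$objects$positions
  r <- round(p[1, 3, 2]) + 1; c_ <- round(p[1, 3, 1]) + 1
  spot3 <- phd$movie$frames[[3]]$pixels[r, c_]
  spot2 <- phd$movie$frames[[2]]$pixels[round(p[1, 2, 2]) + 1,
                                        round(p[1, 2, 1]) + 1]
  expect_lt(spot3, 40)    # background only
  expect_gt(spot2, 100)   # rendered spot
  expect_error(make_track_movie(speed = 50, n_frames = 30, size = 256),
               class = "validation_error")
})
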