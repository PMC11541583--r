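test_that("simple topologies are read correctly from the skeleton", {
  bar <- matrix(FALSE, 100, 100); bar[48:52, 10:90] <- TRUE
  net <- skeleton_graph(bar, 1, prune_len = 10)
  expect_equal(sum(net$nodes$class == "extremity"), 2)
  expect_equal(sum(net$nodes$class %in% c("junction", "master_junction")), 0)
  expect_equal(nrow(net$meshes), 0)

  th <- theta_mask()
  net <- skeleton_graph(th, 1, prune_len = 10)
  ap <- angio_params(net)
  expect_equal(ap[["n_junctions"]], 2)
  expect_equal(ap[["n_master_segments"]], 3)
  expect_equal(ap[["n_meshes"]], 2)

  empty <- skeleton_graph(matrix(FALSE, 32, 32), 1)
  ape <- angio_params(empty)
  expect_true(all(unclass(ape) == 0))
})

test_that("lattice phantom parameters match the generator-graph truth", {
  ph <- make_tube_lattice(rows = 2, cols = 3, edge_len = 100, tube_width = 10,
                          jitter = 0, seed = 1)
  mask <- ph$image$pixels > 0.5 * max(ph$image$pixels)
  net <- skeleton_graph(mask, ph$image$pixel_size, prune_len = 10)
  ap <- angio_params(net)
  tr <- ph$truth$objects
  expect_equal(ap[["n_meshes"]], 6)
  expect_equal(ap[["n_junctions"]], 8)
  expect_equal(ap[["n_master_segments"]], tr$n_master_segments)
  expect_lt(abs(ap[["total_master_length"]] / tr$total_master_len_um - 1),
            0.05)
  expect_lt(abs(ap[["total_mesh_area"]] / sum(tr$face_areas_um2) - 1), 0.10)
  # totals are zero iff their counts are zero
  expect_true(ap[["total_master_length"]] > 0 || ap[["n_master_segments"]] == 0)
})

test_that("Euler face count is consistent on lattice phantoms", {
  for (cfg in list(c(1, 1), c(2, 3), c(3, 2))) {
    ph <- make_tube_lattice(rows = cfg[1], cols = cfg[2], edge_len = 80,
                            tube_width = 8, seed = cfg[1] * 10 + cfg[2])
    mask <- ph$image$pixels > 0.5 * max(ph$image$pixels)
    net <- skeleton_graph(mask, 1, prune_len = 10)
    euler <- nrow(net$segments) - nrow(net$nodes) + net$n_components
    expect_equal(nrow(net$meshes), euler)
    expect_equal(nrow(net$meshes), cfg[1] * cfg[2])
  }
})

test_that("network measurements are robust to rotation", {
  ph <- make_tube_lattice(rows = 2, cols = 2, edge_len = 80, tube_width = 8,
                          seed = 3)
  mask <- ph$image$pixels > 0.5 * max(ph$image$pixels)
  ap <- angio_params(skeleton_graph(mask, 1, 10))
  ap90 <- angio_params(skeleton_graph(t(mask[nrow(mask):1, ]), 1, 10))
  expect_equal(unclass(ap90), unclass(ap))

  rot <- as.matrix(EBImage::rotate(EBImage::Image(mask), 45,
                                   output.dim = c(400, 400))) > 0.5
  ap45 <- angio_params(skeleton_graph(rot, 1, 10))
  expect_equal(ap45[["n_meshes"]], ap[["n_meshes"]])
  expect_equal(ap45[["n_junctions"]], ap[["n_junctions"]])
  expect_equal(ap45[["n_master_segments"]], ap[["n_master_segments"]])
  expect_lt(abs(ap45[["total_master_length"]] / ap[["total_master_length"]] - 1),
            0.07)
  expect_lt(abs(ap45[["total_mesh_area"]] / ap[["total_mesh_area"]] - 1), 0.07)
})

test_that("binarization recovers the planted tube mask", {
  ph <- make_tube_lattice(rows = 2, cols = 2, edge_len = 80, tube_width = 10,
                          noise_sd = 0, seed = 5)
  mask <- binarize_network(ph$image, ball_radius = 40, min_object_area = 50)
  planted <- ph$image$pixels > 0.5 * max(ph$image$pixels)
  expect_false(any(outside_boundary_band(unname(mask), planted)))

  blank <- image_frame(matrix(0, 64, 64), 8L, 1)
  expect_false(any(binarize_network(blank, 10, method = 5,
                                    min_object_area = 0)))
})

test_that("angiogenesis index is a mean of control-normalised ratios", {
  ph <- make_tube_lattice(rows = 2, cols = 3, seed = 2)
  mask <- ph$image$pixels > 0.5 * max(ph$image$pixels)
  ap <- angio_params(skeleton_graph(mask, 1, 10))
  expect_equal(angiogenesis_index(ap, ap)$value, 1.0)

  zeros <- structure(stats::setNames(rep(0, 6), names(unclass(ap))),
                     class = "AngioParams")
  expect_equal(angiogenesis_index(zeros, ap)$value, 0.0)
  doubled <- structure(unclass(ap) * 2, class = "AngioParams")
  expect_equal(angiogenesis_index(doubled, ap)$value, 2.0)
  # homogeneity in the treated arm
  k <- 1.7
  scaled <- structure(unclass(ap) * k, class = "AngioParams")
  expect_equal(angiogenesis_index(scaled, ap)$value, k)
  err <- tryCatch(angiogenesis_index(ap, zeros), condition = identity)
  expect_s3_class(err, "undefined_ratio_error")
  expect_match(conditionMessage(err), "n_junctions")
})
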