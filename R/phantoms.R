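#' Synthetic ground-truthed phantoms
#'
#' Every assay pipeline in this package can be exercised offline on
#' synthetic images whose content is known exactly. Each generator
#' plants objects with the statistical structure its assay assumes —
#' a stellate spheroid with radiating invader cells on an uneven
#' brightfield background, a field of small round spheroids carrying
#' live/dead puncta, a honeycomb-like tube lattice with known topology,
#' or moving Gaussian spots with known speed and missed detections —
#' and returns the image(s) together with a `PhantomTruth` record of
#' what was planted. The imaging model is multiplicative low-order
#' illumination, optional Poisson shot noise on the signal and additive
#' Gaussian read noise; no attempt is made at matrix texture or optical
#' point-spread simulation.
#'
#' @name phantom_forge
NULL

new_phantom_truth <- function(kind, objects, params, seed) {
  structure(list(kind = kind, objects = objects, params = params,
                 seed = seed), class = "PhantomTruth")
}

#' Write a phantom truth sidecar as JSON
#'
#' Masks are not serialised; planted geometry (centres, radii, graphs,
#' trajectories) and the full parameter set are.
#'
#' @param truth `PhantomTruth`.
#' @param path output JSON path.
#' @export
write_phantom_truth <- function(truth, path) {
  keep <- truth
  keep$objects <- lapply(truth$objects, function(o) {
    if (is.matrix(o) && is.logical(o)) NULL else o
  })
  keep$objects <- Filter(Negate(is.null), keep$objects)
  jsonlite::write_json(unclass(keep), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# noise model shared by the generators; img in [0, 1]
apply_noise <- function(img, noise_sd = 0, photons = 0) {
  if (photons > 0)
    img <- matrix(rpois(length(img), pmax(img, 0) * photons) / photons,
                  nrow(img))
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
  pmin(pmax(img, 0), 1)
}

quantize_frame <- function(img01, bit_depth, pixel_size, channel) {
  mx <- 2^bit_depth - 1
  image_frame(round(img01 * mx), bit_depth = bit_depth,
              pixel_size = pixel_size, channel = channel)
}

disc_mask <- function(nr, nc, row, col, r_px) {
  ri <- ceiling(r_px)
  out <- matrix(FALSE, nr, nc)
  r0 <- max(1L, floor(row - ri)); r1 <- min(nr, ceiling(row + ri))
  c0 <- max(1L, floor(col - ri)); c1 <- min(nc, ceiling(col + ri))
  if (r0 > r1 || c0 > c1) return(out)
  out[r0:r1, c0:c1] <- outer((r0:r1) - row, (c0:c1) - col,
                             function(a, b) a^2 + b^2) <= r_px^2
  out
}

add_gaussian_spot <- function(img, row, col, sigma_px, amplitude) {
  half <- ceiling(4 * sigma_px)
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(row - half)); r1 <- min(nr, ceiling(row + half))
  c0 <- max(1L, floor(col - half)); c1 <- min(nc, ceiling(col + half))
  if (r0 > r1 || c0 > c1) return(img)
  g <- outer(exp(-((r0:r1) - row)^2 / (2 * sigma_px^2)),
             exp(-((c0:c1) - col)^2 / (2 * sigma_px^2)))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * g
  img
}

# multiplicative planar illumination field, mean 1, peak-to-peak
# 2*gradient along a fixed oblique direction
illumination_field <- function(nr, nc, gradient) {
  if (gradient == 0) return(matrix(1, nr, nc))
  gx <- matrix(rep(seq(-0.5, 0.5, length.out = nc), each = nr), nr)
  gy <- matrix(rep(seq(-0.5, 0.5, length.out = nr), nc), nr)
  1 + gradient * (0.6 * gx + 0.4 * gy) * 2
}

#' Stellate spheroid phantom
#'
#' One dense circular core with `n_strands` radial chains of small
#' round invader cells, rendered brightfield-style (objects darker than
#' the background) under a planar illumination gradient with
#' Poisson-Gaussian noise. The truth records the exact rasterised core
#' mask and invader-cell mask and their areas.
#'
#' @param core_radius core radius in um (default 150).
#' @param n_strands number of radial invader strands (default 12).
#' @param strand_length radial extent of each strand in um
#'   (default 200).
#' @param cell_density invader cells per um of strand (default 0.02).
#' @param illum_gradient fractional amplitude of the illumination
#'   plane (default 0.1).
#' @param noise_sd Gaussian read-noise standard deviation as a
#'   fraction of full scale (default 0.02).
#' @param photons Poisson photon budget at full scale; 0 disables shot
#'   noise (default 0).
#' @param seed integer RNG seed.
#' @param size image side in pixels (default 512).
#' @param pixel_size um per pixel (default 2).
#' @param bit_depth 8 or 16 (default 16).
#' @return list with `image` (`ImageFrame`, channel "brightfield") and
#'   `truth` (`PhantomTruth` whose objects include `core_mask`,
#'   `invader_mask`, `core_area_um2`, `invader_area_um2`).
#' @export
make_stellate <- function(core_radius = 150, n_strands = 12,
                          strand_length = 200, cell_density = 0.02,
                          illum_gradient = 0.1, noise_sd = 0.02,
                          photons = 0, seed = 0, size = 512,
                          pixel_size = 2, bit_depth = 16) {
  check_scalar_pos(core_radius, "core_radius")
  check_scalar_nonneg(n_strands, "n_strands")
  set.seed(seed)
  half_um <- size * pixel_size / 2
  cell_r <- 6                     # invader cell radius, um
  gap <- 15                      # strand take-off gap from the core, um
  reach <- core_radius + if (n_strands > 0) gap + strand_length + cell_r else 0
  if (reach > half_um - 4 * pixel_size)
    stop_cm("validation_error",
            "phantom geometry exceeds the image bounds")
  ctr <- (size + 1) / 2
  bg <- 0.75; core_int <- 0.35; cell_int <- 0.45

  core_mask <- disc_mask(size, size, ctr, ctr,
                         um_to_px(core_radius, pixel_size))
  invader_mask <- matrix(FALSE, size, size)
  strands <- list()
  if (n_strands > 0) {
    base <- runif(1, 0, 2 * pi)
    angles <- base + (0:(n_strands - 1)) * 2 * pi / n_strands +
      runif(n_strands, -0.1, 0.1)
    n_cells <- max(1L, round(strand_length * cell_density))
    for (s in seq_len(n_strands)) {
      cells <- list()
      for (i in seq_len(n_cells)) {
        r_um <- core_radius + gap + (i - 0.5) * strand_length / n_cells +
          runif(1, -3, 3)
        a <- angles[s] + runif(1, -0.03, 0.03)
        row <- ctr + um_to_px(r_um, pixel_size) * sin(a)
        col <- ctr + um_to_px(r_um, pixel_size) * cos(a)
        invader_mask <- invader_mask |
          disc_mask(size, size, row, col, um_to_px(cell_r, pixel_size))
        cells[[i]] <- list(x_um = (col - 1) * pixel_size,
                           y_um = (row - 1) * pixel_size, r_um = cell_r)
      }
      strands[[s]] <- list(angle = angles[s], cells = cells)
    }
  }
  invader_mask <- invader_mask & !core_mask
  img <- matrix(bg, size, size)
  img[core_mask] <- core_int
  img[invader_mask] <- cell_int
  img <- img * illumination_field(size, size, illum_gradient)
  img <- apply_noise(img, noise_sd, photons)
  truth <- new_phantom_truth(
    "stellate",
    list(core_mask = core_mask, invader_mask = invader_mask,
         core_area_um2 = sum(core_mask) * pixel_size^2,
         core_area_analytic_um2 = pi * core_radius^2,
         invader_area_um2 = sum(invader_mask) * pixel_size^2,
         strands = strands),
    params = list(core_radius = core_radius, n_strands = n_strands,
                  strand_length = strand_length,
                  cell_density = cell_density, cell_radius = cell_r,
                  illum_gradient = illum_gradient, noise_sd = noise_sd,
                  photons = photons, size = size,
                  pixel_size = pixel_size, bit_depth = bit_depth),
    seed = seed)
  list(image = quantize_frame(img, bit_depth, pixel_size, "brightfield"),
       truth = truth)
}

#' Organoid field phantom (two channels)
#'
#' Many small round spheroids; the green channel carries the spheroid
#' bodies plus bright live-cell puncta, the orange channel the
#' dead-cell puncta. Puncta are isotropic Gaussians (sigma =
#' diameter/4): a bright centre with radially decreasing intensity,
#' matching the dot detector's target profile.
#'
#' @param n_spheroids number of spheroids (default 12).
#' @param radius_range um range of spheroid radii (default c(20, 40)).
#' @param live_range,dead_range integer ranges of per-spheroid live and
#'   dead cell counts (defaults c(2, 6) and c(0, 4)).
#' @param min_separation minimum edge-to-edge spheroid separation in um
#'   (default 30).
#' @param dot_diameter cell-punctum diameter in um (default 8).
#' @param noise_sd,photons noise model, as in [make_stellate()].
#' @param seed,size,pixel_size,bit_depth as in [make_stellate()]
#'   (pixel_size defaults to 1 here).
#' @return list with `green`, `orange` (`ImageFrame`s) and `truth`
#'   (per-spheroid centre, radius, live/dead point lists; masks).
#' @export
make_organoid_field <- function(n_spheroids = 12, radius_range = c(20, 40),
                                live_range = c(2, 6), dead_range = c(0, 4),
                                min_separation = 30, dot_diameter = 8,
                                noise_sd = 0.01, photons = 0, seed = 0,
                                size = 512, pixel_size = 1, bit_depth = 16) {
  check_scalar_nonneg(n_spheroids, "n_spheroids")
  set.seed(seed)
  margin <- max(radius_range) + 10
  if (2 * margin >= size * pixel_size && n_spheroids > 0)
    stop_cm("validation_error", "image too small for the radius range")
  centres <- matrix(numeric(0), 0, 2); radii <- numeric(0)
  tries <- 0L
  while (nrow(centres) < n_spheroids) {
    tries <- tries + 1L
    if (tries > 5000L)
      stop_cm("packing_error",
              "could not place ", n_spheroids, " spheroids at separation ",
              min_separation, " um")
    r <- runif(1, radius_range[1], radius_range[2])
    x <- runif(1, margin, size * pixel_size - margin)
    y <- runif(1, margin, size * pixel_size - margin)
    if (nrow(centres)) {
      d <- sqrt((centres[, 1] - x)^2 + (centres[, 2] - y)^2)
      if (any(d < r + radii + min_separation)) next
    }
    centres <- rbind(centres, c(x, y)); radii <- c(radii, r)
  }
  green <- matrix(0, size, size); orange <- matrix(0, size, size)
  body_int <- 0.3; live_amp <- 0.65; dead_amp <- 0.9
  dot_sigma <- dot_diameter / 4
  spheroids <- list()
  place_points <- function(cx, cy, r, n) {
    pts <- matrix(numeric(0), 0, 2); t2 <- 0L
    while (nrow(pts) < n && t2 < 500L) {
      t2 <- t2 + 1L
      a <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.7 * r
      p <- c(cx + rr * cos(a), cy + rr * sin(a))
      if (nrow(pts)) {
        if (any(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) <
                1.5 * dot_diameter)) next
      }
      pts <- rbind(pts, p)
    }
    pts
  }
  for (i in seq_len(n_spheroids)) {
    cx <- centres[i, 1]; cy <- centres[i, 2]; r <- radii[i]
    row <- cy / pixel_size + 1; col <- cx / pixel_size + 1
    body <- disc_mask(size, size, row, col, um_to_px(r, pixel_size))
    green[body] <- pmax(green[body], body_int)
    lv <- place_points(cx, cy, r, sample(live_range[1]:live_range[2], 1))
    dd <- place_points(cx, cy, r, sample(dead_range[1]:dead_range[2], 1))
    for (j in seq_len(nrow(lv)))
      green <- add_gaussian_spot(green, lv[j, 2] / pixel_size + 1,
                                 lv[j, 1] / pixel_size + 1,
                                 um_to_px(dot_sigma, pixel_size), live_amp)
    for (j in seq_len(nrow(dd)))
      orange <- add_gaussian_spot(orange, dd[j, 2] / pixel_size + 1,
                                  dd[j, 1] / pixel_size + 1,
                                  um_to_px(dot_sigma, pixel_size), dead_amp)
    spheroids[[i]] <- list(
      x_um = cx, y_um = cy, r_um = r,
      area_um2 = sum(body) * pixel_size^2,
      live = if (nrow(lv)) data.frame(x_um = lv[, 1], y_um = lv[, 2])
             else data.frame(x_um = numeric(0), y_um = numeric(0)),
      dead = if (nrow(dd)) data.frame(x_um = dd[, 1], y_um = dd[, 2])
             else data.frame(x_um = numeric(0), y_um = numeric(0)))
  }
  green <- apply_noise(green, noise_sd, photons)
  orange <- apply_noise(orange, noise_sd, photons)
  truth <- new_phantom_truth(
    "organoid",
    list(spheroids = spheroids,
         n_spheroids = n_spheroids,
         total_live = sum(vapply(spheroids, function(s) nrow(s$live), numeric(1))),
         total_dead = sum(vapply(spheroids, function(s) nrow(s$dead), numeric(1)))),
    params = list(n_spheroids = n_spheroids, radius_range = radius_range,
                  live_range = live_range, dead_range = dead_range,
                  min_separation = min_separation,
                  dot_diameter = dot_diameter, noise_sd = noise_sd,
                  photons = photons, size = size, pixel_size = pixel_size,
                  bit_depth = bit_depth),
    seed = seed)
  list(green = quantize_frame(green, bit_depth, pixel_size, "calcein"),
       orange = quantize_frame(orange, bit_depth, pixel_size, "ethidium"),
       truth = truth)
}

# contract degree-2 vertices of a truth graph; returns the contracted
# edge list (used for the master-segment oracle: a skeleton tracer
# cannot see degree-2 corner nodes, so the planted graph is stored in
# the same contracted form)
contract_degree2 <- function(edges, degrees) {
  repeat {
    deg <- table(factor(c(edges$from, edges$to),
                        levels = seq_along(degrees)))
    v <- which(as.numeric(deg) == 2)
    v <- v[vapply(v, function(x)
      sum(edges$from == x & edges$to == x) == 0, logical(1))]
    if (!length(v)) break
    vi <- v[1]
    ei <- which(edges$from == vi | edges$to == vi)
    if (length(ei) != 2L) break
    e1 <- edges[ei[1], ]; e2 <- edges[ei[2], ]
    a <- if (e1$from == vi) e1$to else e1$from
    b <- if (e2$from == vi) e2$to else e2$from
    edges <- edges[-ei, , drop = FALSE]
    edges <- rbind(edges, data.frame(from = min(a, b), to = max(a, b),
                                     len = e1$len + e2$len))
  }
  edges
}

#' Tube-lattice phantom
#'
#' A rectangular (optionally jittered) lattice of bright tubes. The
#' truth stores the generating graph: node positions and degrees, edge
#' lengths, face count `rows * cols` and per-face polygon areas, plus
#' the master-segment totals of the degree-2-contracted graph (what a
#' skeleton tracer measures, since degree-2 corners are invisible to
#' it).
#'
#' @param rows,cols lattice cells per side (>= 1 each).
#' @param edge_len lattice edge length in um (default 100).
#' @param tube_width tube thickness in um (default 10; must be smaller
#'   than `edge_len`).
#' @param jitter uniform node-position jitter in um (default 0).
#' @param intensity tube intensity as a fraction of full scale.
#' @param noise_sd,photons,seed,pixel_size,bit_depth as above.
#' @param margin border margin in um (default 30).
#' @return list with `image` (`ImageFrame`) and `truth`.
#' @export
make_tube_lattice <- function(rows = 3, cols = 4, edge_len = 100,
                              tube_width = 10, jitter = 0,
                              intensity = 0.8, noise_sd = 0, photons = 0,
                              seed = 0, pixel_size = 1, bit_depth = 16,
                              margin = 30) {
  if (rows < 1 || cols < 1)
    stop_cm("validation_error", "rows and cols must be >= 1")
  if (tube_width >= edge_len)
    stop_cm("validation_error",
            "tube_width must be smaller than edge_len (tubes would merge)")
  set.seed(seed)
  nrn <- rows + 1L; ncn <- cols + 1L
  xs <- margin + (0:cols) * edge_len
  ys <- margin + (0:rows) * edge_len
  nx <- outer(rep(1, nrn), xs) + matrix(runif(nrn * ncn, -jitter, jitter), nrn)
  ny <- outer(ys, rep(1, ncn)) + matrix(runif(nrn * ncn, -jitter, jitter), nrn)
  W_um <- 2 * margin + cols * edge_len
  H_um <- 2 * margin + rows * edge_len
  nc_px <- ceiling(W_um / pixel_size); nr_px <- ceiling(H_um / pixel_size)
  nid <- function(i, j) (j - 1L) * nrn + i   # node index, column-major
  edges <- data.frame(from = integer(0), to = integer(0), len = numeric(0))
  seg_ends <- list()
  for (i in seq_len(nrn)) for (j in seq_len(ncn)) {
    if (j < ncn) {
      a <- nid(i, j); b <- nid(i, j + 1L)
      len <- sqrt((nx[i, j] - nx[i, j + 1])^2 + (ny[i, j] - ny[i, j + 1])^2)
      edges <- rbind(edges, data.frame(from = a, to = b, len = len))
      seg_ends[[length(seg_ends) + 1]] <-
        c(nx[i, j], ny[i, j], nx[i, j + 1], ny[i, j + 1])
    }
    if (i < nrn) {
      a <- nid(i, j); b <- nid(i + 1L, j)
      len <- sqrt((nx[i, j] - nx[i + 1, j])^2 + (ny[i, j] - ny[i + 1, j])^2)
      edges <- rbind(edges, data.frame(from = a, to = b, len = len))
      seg_ends[[length(seg_ends) + 1]] <-
        c(nx[i, j], ny[i, j], nx[i + 1, j], ny[i + 1, j])
    }
  }
  img <- matrix(0, nr_px, nc_px)
  hw_px <- um_to_px(tube_width / 2, pixel_size)
  for (s in seg_ends) {
    x1 <- s[1] / pixel_size + 1; y1 <- s[2] / pixel_size + 1
    x2 <- s[3] / pixel_size + 1; y2 <- s[4] / pixel_size + 1
    r0 <- max(1L, floor(min(y1, y2) - hw_px - 1))
    r1 <- min(nr_px, ceiling(max(y1, y2) + hw_px + 1))
    c0 <- max(1L, floor(min(x1, x2) - hw_px - 1))
    c1 <- min(nc_px, ceiling(max(x1, x2) + hw_px + 1))
    rr <- r0:r1; cc <- c0:c1
    px <- matrix(rep(cc, each = length(rr)), length(rr))
    py <- matrix(rep(rr, length(cc)), length(rr))
    vx <- x2 - x1; vy <- y2 - y1; L2 <- vx^2 + vy^2
    t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
    d2 <- (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
    img[rr, cc] <- pmax(img[rr, cc], intensity * (d2 <= hw_px^2))
  }
  img <- apply_noise(img, noise_sd, photons)
  degrees <- rep(0L, nrn * ncn)
  for (k in seq_len(nrow(edges))) {
    degrees[edges$from[k]] <- degrees[edges$from[k]] + 1L
    degrees[edges$to[k]] <- degrees[edges$to[k]] + 1L
  }
  faces <- list()
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    poly <- rbind(c(nx[i, j], ny[i, j]), c(nx[i, j + 1], ny[i, j + 1]),
                  c(nx[i + 1, j + 1], ny[i + 1, j + 1]),
                  c(nx[i + 1, j], ny[i + 1, j]))
    faces[[length(faces) + 1]] <- list(area_um2 = polygon_area(poly))
  }
  contracted <- contract_degree2(edges, degrees)
  cdeg <- table(factor(c(contracted$from, contracted$to),
                       levels = seq_along(degrees)))
  jn <- which(as.numeric(cdeg) >= 3)
  master <- contracted[contracted$from %in% jn & contracted$to %in% jn, ]
  truth <- new_phantom_truth(
    "tubes",
    list(node_x = as.vector(nx), node_y = as.vector(ny),
         node_degree = degrees,
         n_junctions = sum(degrees >= 3),
         edges = edges,
         total_edge_len_um = sum(edges$len),
         n_meshes = rows * cols,
         face_areas_um2 = vapply(faces, `[[`, numeric(1), "area_um2"),
         n_master_segments = nrow(master),
         total_master_len_um = sum(master$len),
         n_master_junctions = length(unique(c(master$from, master$to)))),
    params = list(rows = rows, cols = cols, edge_len = edge_len,
                  tube_width = tube_width, jitter = jitter,
                  intensity = intensity, noise_sd = noise_sd,
                  photons = photons, pixel_size = pixel_size,
                  bit_depth = bit_depth, margin = margin),
    seed = seed)
  list(image = quantize_frame(img, bit_depth, pixel_size, "tubes"),
       truth = truth)
}

#' Time-lapse phantom of moving spots
#'
#' Straight-line constant-speed particles rendered as Gaussian spots,
#' with optional per-particle dropout frames (missed detections) and
#' uniform positional jitter. The truth holds the exact per-frame
#' positions and dropout flags.
#'
#' @param n_particles number of particles (default 8).
#' @param speed um per frame (default 5).
#' @param n_frames frames in the movie (default 30).
#' @param dropout_frames either a list of integer frame vectors (one
#'   per particle) or a single dropout probability in `[0, 1)` applied
#'   independently per particle and frame.
#' @param max_jitter uniform positional jitter amplitude in um
#'   (default 0).
#' @param min_separation smallest allowed distance between any two
#'   particles in any frame (default one spot diameter): the phantom
#'   emulates distinguishable cells, so planted trajectories never
#'   approach closer than the detector can resolve.
#' @param diameter rendered spot diameter in um (default 18; Gaussian
#'   sigma is `diameter/4`).
#' @param frame_spacing seconds between frames (default 1200 = 20 min).
#' @param peak_intensity spot peak in native 8-bit units (default 150,
#'   inside the 30-230 detection window).
#' @param seed,size,pixel_size as above; frames are 8-bit.
#' @return list with `movie` (`ImageStack`, axis "t") and `truth`
#'   (positions array, dropout flags, planted speed).
#' @export
make_track_movie <- function(n_particles = 8, speed = 5, n_frames = 30,
                             dropout_frames = 0, max_jitter = 0,
                             min_separation = 18, diameter = 18,
                             frame_spacing = 1200, peak_intensity = 150,
                             seed = 0, size = 256, pixel_size = 1) {
  check_scalar_pos(n_frames, "n_frames")
  set.seed(seed)
  fov <- size * pixel_size
  margin <- diameter + 5
  reach <- speed * (n_frames - 1)
  if (reach > fov - 2 * margin)
    stop_cm("validation_error",
            "trajectories exceed the image bounds; reduce speed or frames")
  if (is.numeric(dropout_frames) && length(dropout_frames) == 1L) {
    p <- dropout_frames
    dropout_frames <- lapply(seq_len(n_particles), function(i)
      which(runif(n_frames) < p))
  }
  if (length(dropout_frames) != n_particles)
    stop_cm("validation_error",
            "dropout_frames must be a probability or one vector per particle")
  pos <- array(NA_real_, c(n_particles, n_frames, 2))
  dropped <- matrix(FALSE, n_particles, n_frames)
  for (i in seq_len(n_particles)) {
    placed <- FALSE
    for (try in 1:500) {
      th <- runif(1, 0, 2 * pi)
      dx <- reach * cos(th); dy <- reach * sin(th)
      x0 <- runif(1, margin + max(0, -dx), fov - margin - max(0, dx))
      y0 <- runif(1, margin + max(0, -dy), fov - margin - max(0, dy))
      xs <- x0 + (0:(n_frames - 1)) * speed * cos(th)
      ys <- y0 + (0:(n_frames - 1)) * speed * sin(th)
      if (i > 1) {
        dmin <- min(vapply(seq_len(i - 1), function(j)
          min(sqrt((pos[j, , 1] - xs)^2 + (pos[j, , 2] - ys)^2)),
          numeric(1)))
        if (dmin < min_separation) next
      }
      jx <- if (max_jitter > 0) runif(n_frames, -max_jitter, max_jitter)
            else 0
      jy <- if (max_jitter > 0) runif(n_frames, -max_jitter, max_jitter)
            else 0
      pos[i, , 1] <- xs + jx
      pos[i, , 2] <- ys + jy
      placed <- TRUE
      break
    }
    if (!placed)
      stop_cm("packing_error",
              "could not place ", n_particles,
              " separated trajectories; reduce count or separation")
    dropped[i, dropout_frames[[i]]] <- TRUE
  }
  sig_px <- um_to_px(diameter / 4, pixel_size)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(10 / 255, size, size)   # dim uniform background
    for (i in seq_len(n_particles)) {
      if (dropped[i, f]) next
      img <- add_gaussian_spot(img, pos[i, f, 2] / pixel_size + 1,
                               pos[i, f, 1] / pixel_size + 1,
                               sig_px, (peak_intensity - 10) / 255)
    }
    img <- apply_noise(img, noise_sd = 2 / 255, photons = 0)
    frames[[f]] <- quantize_frame(img, 8L, pixel_size, "mKO2")
  }
  truth <- new_phantom_truth(
    "tracks",
    list(positions = pos, dropped = dropped, speed_um_per_frame = speed),
    params = list(n_particles = n_particles, speed = speed,
                  n_frames = n_frames, max_jitter = max_jitter,
                  diameter = diameter, frame_spacing = frame_spacing,
                  peak_intensity = peak_intensity, size = size,
                  pixel_size = pixel_size),
    seed = seed)
  list(movie = image_stack(frames, axis = "t", spacing = frame_spacing),
       truth = truth)
}
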