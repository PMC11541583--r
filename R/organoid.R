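#' Organoid-field live/dead cytometry
#'
#' Analyses two-channel fluorescence fields of many small round
#' spheroids, stained so that live cells are bright green puncta
#' (calcein-AM) and dead cells bright orange puncta (ethidium
#' homodimer). Dead cells are found by two cooperating engines — a
#' dot-like-structure (blob) detector for puncta with a bright centre
#' and radially decreasing intensity, and a plain intensity-threshold
#' detector — whose masks are merged; spheroids themselves are detected
#' by a double threshold on intensity and area.
#'
#' @name organoid_field
NULL

resolve_threshold <- function(pixels, thresh, type = c("relative", "absolute")) {
  type <- match.arg(type)
  if (type == "relative") thresh * max(pixels) else thresh
}

new_dot_detection <- function(points, mask) {
  structure(list(points = points, mask = mask), class = "DotDetection")
}

engine_threshold <- function(pixels, thr) {
  mask <- pixels > thr
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  k <- max(lab)
  pts <- if (k == 0) {
    cbind(row = numeric(0), col = numeric(0), intensity = numeric(0))
  } else {
    t(vapply(seq_len(k), function(i) {
      idx <- which(lab == i, arr.ind = TRUE)
      c(mean(idx[, 1]), mean(idx[, 2]), max(pixels[idx]))
    }, numeric(3)))
  }
  list(mask = mask, points = pts)
}

#' Detect dead cells with merged dual engines
#'
#' Engine 1 finds dot-like structures as maxima of a
#' Laplacian-of-Gaussian response at the cell scale, keeping only maxima
#' whose intensity falls by at least `centre_drop` within one cell
#' radius (the bright-centre / radial-gradient signature). Engine 2 is
#' an intensity-threshold detection of stained areas. The final mask is
#' the union of both engines' masks; final points are the engine-1
#' maxima plus centroids of engine-2 components not already claimed by
#' an engine-1 point.
#'
#' @param dead_channel `ImageFrame` of the dead-cell stain.
#' @param cell_diameter expected dead-cell diameter in micrometres
#'   (default 8; must exceed 2 pixels).
#' @param intensity_thresh threshold value; interpreted per
#'   `thresh_type`.
#' @param thresh_type `"relative"` (fraction of the channel maximum,
#'   default) or `"absolute"`.
#' @param centre_drop required fractional intensity drop from peak to
#'   the ring one radius out (default 0.3).
#' @return a `DotDetection`: `points` (x_um, y_um, intensity) and
#'   `mask` (logical).
#' @export
detect_dead_cells <- function(dead_channel, cell_diameter = 8,
                              intensity_thresh = 0.5,
                              thresh_type = "relative",
                              centre_drop = 0.3) {
  px <- dead_channel$pixels
  psz <- dead_channel$pixel_size
  d_px <- um_to_px(cell_diameter, psz)
  if (d_px <= 2)
    stop_cm("validation_error",
            "cell_diameter must exceed 2 pixels at this calibration")
  thr <- resolve_threshold(px, intensity_thresh, thresh_type)
  if (max(px) == 0)
    return(new_dot_detection(
      data.frame(x_um = numeric(0), y_um = numeric(0),
                 intensity = numeric(0), engine = integer(0)),
      matrix(FALSE, nrow(px), ncol(px))))

  sigma <- d_px / (2 * sqrt(2))
  mx1 <- log_maxima(px, sigma, min_sep_px = d_px / 2)
  r_px <- d_px / 2
  keep <- logical(nrow(mx1))
  for (i in seq_len(nrow(mx1))) {
    peak <- px[mx1[i, 1], mx1[i, 2]]
    ring <- ring_mean(px, mx1[i, 1], mx1[i, 2], r_px)
    keep[i] <- peak > 0 && is.finite(ring) &&
      (peak - ring) / peak >= centre_drop && peak > thr
  }
  mx1 <- mx1[keep, , drop = FALSE]
  mask1 <- disc_stamp(nrow(px), ncol(px), mx1, r_px)

  e2 <- engine_threshold(px, thr)
  mask <- mask1 | e2$mask

  pts <- if (nrow(mx1)) {
    data.frame(x_um = (mx1[, 2] - 1) * psz, y_um = (mx1[, 1] - 1) * psz,
               intensity = px[mx1], engine = 1L)
  } else {
    data.frame(x_um = numeric(0), y_um = numeric(0),
               intensity = numeric(0), engine = integer(0))
  }
  # engine-2 component centroids not claimed by an engine-1 maximum
  if (nrow(e2$points)) {
    claimed <- logical(nrow(e2$points))
    if (nrow(mx1)) {
      lab2 <- as.matrix(EBImage::bwlabel(EBImage::Image(e2$mask)))
      claimed_labs <- unique(lab2[mx1])
      comp_lab <- lab2[cbind(round(e2$points[, 1]), round(e2$points[, 2]))]
      claimed <- comp_lab %in% claimed_labs[claimed_labs > 0]
    }
    add <- e2$points[!claimed, , drop = FALSE]
    if (nrow(add))
      pts <- rbind(pts, data.frame(
        x_um = (add[, 2] - 1) * psz, y_um = (add[, 1] - 1) * psz,
        intensity = add[, 3], engine = 2L))
  }
  pts <- enforce_min_separation(pts, min_sep = cell_diameter / 2)
  new_dot_detection(pts, mask)
}

#' Detect live cells by intensity threshold
#'
#' Single-engine detection: threshold, connected components, one point
#' per component at its centroid.
#'
#' @inheritParams detect_dead_cells
#' @param live_channel `ImageFrame` of the live-cell stain.
#' @return a `DotDetection`.
#' @export
detect_live_cells <- function(live_channel, cell_diameter = 8,
                              intensity_thresh = 0.6,
                              thresh_type = "relative") {
  px <- live_channel$pixels
  psz <- live_channel$pixel_size
  if (max(px) == 0)
    return(new_dot_detection(
      data.frame(x_um = numeric(0), y_um = numeric(0),
                 intensity = numeric(0), engine = integer(0)),
      matrix(FALSE, nrow(px), ncol(px))))
  thr <- resolve_threshold(px, intensity_thresh, thresh_type)
  e2 <- engine_threshold(px, thr)
  pts <- if (nrow(e2$points)) {
    data.frame(x_um = (e2$points[, 2] - 1) * psz,
               y_um = (e2$points[, 1] - 1) * psz,
               intensity = e2$points[, 3], engine = 2L)
  } else {
    data.frame(x_um = numeric(0), y_um = numeric(0),
               intensity = numeric(0), engine = integer(0))
  }
  pts <- enforce_min_separation(pts, min_sep = cell_diameter / 2)
  new_dot_detection(pts, e2$mask)
}

#' Detect spheroids by a double threshold on intensity and area
#'
#' Threshold the (live) channel, fill holes, label connected components
#' and discard components below `min_area` (and above `max_area` when
#' given); survivors are relabelled 1..K.
#'
#' @param live_channel `ImageFrame`.
#' @param intensity_thresh,thresh_type as in [detect_dead_cells()].
#' @param min_area minimum spheroid area in um^2. The default is the
#'   area of a disc three cell diameters across (a spheroid must exceed
#'   a few cells).
#' @param max_area optional maximum area in um^2.
#' @param cell_diameter used only for the `min_area` default.
#' @return integer `LabelMask` (0 = background, labels 1..K).
#' @export
detect_spheroids <- function(live_channel, intensity_thresh = 0.15,
                             thresh_type = "relative",
                             min_area = NULL, max_area = NULL,
                             cell_diameter = 8) {
  if (is.null(min_area)) min_area <- pi * (1.5 * cell_diameter)^2
  check_scalar_nonneg(min_area, "min_area")
  px <- live_channel$pixels
  psz <- live_channel$pixel_size
  if (max(px) == 0) return(matrix(0L, nrow(px), ncol(px)))
  thr <- resolve_threshold(px, intensity_thresh, thresh_type)
  mask <- fill_holes(px > thr)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) == 0) return(matrix(0L, nrow(px), ncol(px)))
  areas <- tabulate(lab[lab > 0]) * psz^2
  drop <- which(areas < min_area)
  if (!is.null(max_area)) drop <- union(drop, which(areas > max_area))
  lab[lab %in% drop] <- 0L
  relabel_mask(lab)
}

#' Per-spheroid statistics
#'
#' For each labelled spheroid: area, circularity, counts of live/dead
#' detections whose coordinates fall inside the spheroid footprint
#' (boundary pixels count as inside), and mean channel intensity over
#' the member dots' footprints. The field summary is the spheroid count.
#'
#' @param spheroids integer `LabelMask` from [detect_spheroids()].
#' @param live,dead `DotDetection` objects.
#' @param live_channel,dead_channel the corresponding `ImageFrame`s.
#' @param pixel_size micrometres per pixel.
#' @return list with `records` (data.frame of `SpheroidRecord` rows) and
#'   `summary` (data.frame with `spheroid_count`).
#' @export
spheroid_stats <- function(spheroids, live, dead,
                           live_channel, dead_channel, pixel_size) {
  if (!identical(dim(spheroids), dim(live_channel$pixels)) ||
      !identical(dim(spheroids), dim(dead_channel$pixels)))
    stop_cm("validation_error", "mask and channels must share geometry")
  check_scalar_pos(pixel_size, "pixel_size")
  k <- max(spheroids)
  rec <- data.frame(spheroid_id = integer(0), area_um2 = numeric(0),
                    circularity = numeric(0), live_count = integer(0),
                    dead_count = integer(0), live_mean_int = numeric(0),
                    dead_mean_int = numeric(0))
  point_labels <- function(det) {
    if (!nrow(det$points)) return(integer(0))
    r <- pmin(pmax(round(det$points$y_um / pixel_size) + 1, 1), nrow(spheroids))
    c_ <- pmin(pmax(round(det$points$x_um / pixel_size) + 1, 1), ncol(spheroids))
    spheroids[cbind(r, c_)]
  }
  live_lab <- point_labels(live)
  dead_lab <- point_labels(dead)
  for (i in seq_len(k)) {
    m <- spheroids == i
    rm_ <- region_metrics(m, pixel_size)
    live_fp <- live$mask & m
    dead_fp <- dead$mask & m
    rec <- rbind(rec, data.frame(
      spheroid_id = i,
      area_um2 = rm_$area,
      circularity = rm_$circularity,
      live_count = sum(live_lab == i),
      dead_count = sum(dead_lab == i),
      live_mean_int = if (any(live_fp))
        mean(live_channel$pixels[live_fp]) else NA_real_,
      dead_mean_int = if (any(dead_fp))
        mean(dead_channel$pixels[dead_fp]) else NA_real_))
  }
  list(records = rec, summary = data.frame(spheroid_count = k))
}

#' Maximum intensity projection of a z-stack
#'
#' @param stack an [image_stack()] with axis `"z"`.
#' @return `ImageFrame` of the per-pixel maximum over planes.
#' @export
max_projection <- function(stack) {
  if (!is_image_stack(stack))
    stop_cm("validation_error", "input must be an ImageStack")
  if (stack$axis != "z")
    stop_cm("validation_error",
            "maximum projection is defined for axis \"z\" stacks")
  out <- Reduce(pmax, lapply(stack$frames, `[[`, "pixels"))
  f1 <- stack$frames[[1]]
  image_frame(out, f1$bit_depth, f1$pixel_size, f1$channel)
}

# -- small helpers -----------------------------------------------------------

# mean intensity on a one-pixel-wide ring of radius r_px around (row, col)
ring_mean <- function(pixels, row, col, r_px) {
  th <- seq(0, 2 * pi, length.out = max(8L, ceiling(2 * pi * r_px)) + 1L)[-1]
  rr <- round(row + r_px * sin(th)); cc <- round(col + r_px * cos(th))
  ok <- rr >= 1 & rr <= nrow(pixels) & cc >= 1 & cc <= ncol(pixels)
  if (!any(ok)) return(NA_real_)
  mean(pixels[cbind(rr[ok], cc[ok])])
}

# union of discs of radius r_px stamped at (row, col) positions
disc_stamp <- function(nr, nc, centres, r_px) {
  mask <- matrix(FALSE, nr, nc)
  if (!nrow(centres)) return(mask)
  ri <- ceiling(r_px)
  for (i in seq_len(nrow(centres))) {
    r0 <- max(1L, centres[i, 1] - ri); r1 <- min(nr, centres[i, 1] + ri)
    c0 <- max(1L, centres[i, 2] - ri); c1 <- min(nc, centres[i, 2] + ri)
    sub <- outer((r0:r1) - centres[i, 1], (c0:c1) - centres[i, 2],
                 function(a, b) a^2 + b^2) <= r_px^2
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | sub
  }
  mask
}

# drop points closer than min_sep (um) to an earlier, brighter point
enforce_min_separation <- function(pts, min_sep) {
  if (nrow(pts) < 2) return(pts)
  ord <- order(-pts$intensity, pts$y_um, pts$x_um)
  pts <- pts[ord, , drop = FALSE]
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- pts[keep, , drop = FALSE]
    d2 <- (prev$x_um - pts$x_um[i])^2 + (prev$y_um - pts$y_um[i])^2
    if (all(d2 >= min_sep^2)) keep[i] <- TRUE
  }
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
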