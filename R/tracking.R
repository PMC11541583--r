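#' Spot detection and track linking for cell-migration analysis
#'
#' Bright, roughly Gaussian cell spots are detected per frame as maxima
#' of a Laplacian-of-Gaussian response at the cell scale, filtered by an
#' intensity window, and localised to sub-pixel precision by an
#' intensity-weighted centroid. Detections are linked frame to frame by
#' globally optimal assignment (minimum total squared displacement among
#' candidate pairs within a distance gate), and broken tracks are
#' bridged across short detection gaps. Defaults mirror common practice
#' for prostate-cancer cells migrating on bone-matrix scaffolds:
#' estimated diameter 18 um, intensity window 30-230, distance gate
#' 20 um, maximum gap 5 frames, one frame per 20 min.
#'
#' @name motion_morphometry
NULL

#' Detect spots in one frame
#'
#' @param frame `ImageFrame`.
#' @param diameter estimated spot diameter in um (default 18; must
#'   exceed two pixels).
#' @param intensity_window `c(lo, hi)` window on the peak intensity in
#'   native units (default `c(30, 230)`); spots outside are discarded.
#' @return data.frame with `x_um`, `y_um`, `intensity` (one row per
#'   spot; empty for a blank frame).
#' @export
detect_spots <- function(frame, diameter = 18,
                         intensity_window = c(30, 230)) {
  px <- frame$pixels
  psz <- frame$pixel_size
  d_px <- um_to_px(diameter, psz)
  if (d_px <= 2)
    stop_cm("validation_error",
            "diameter must exceed 2 pixels at this calibration")
  if (length(intensity_window) != 2L ||
      intensity_window[1] >= intensity_window[2])
    stop_cm("validation_error", "intensity_window must be (lo, hi), lo < hi")
  if (max(px) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  sigma <- d_px / (2 * sqrt(2))
  mx <- log_maxima(px, sigma, min_sep_px = d_px / 2)
  if (!nrow(mx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  peak <- px[mx]
  keep <- peak >= intensity_window[1] & peak <= intensity_window[2]
  mx <- mx[keep, , drop = FALSE]
  if (!nrow(mx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  half <- max(2L, round(d_px / 3))
  rc <- t(vapply(seq_len(nrow(mx)), function(i)
    refine_centroid(px, mx[i, 1], mx[i, 2], half), numeric(2)))
  out <- data.frame(x_um = (rc[, 2] - 1) * psz, y_um = (rc[, 1] - 1) * psz,
                    intensity = px[mx])
  out[order(out$y_um, out$x_um), , drop = FALSE]
}

#' Detect spots on every frame of a time-lapse stack
#'
#' @param stack `ImageStack` with axis `"t"`.
#' @inheritParams detect_spots
#' @return list of per-frame spot data.frames (a `SpotSet`).
#' @export
detect_spots_stack <- function(stack, diameter = 18,
                               intensity_window = c(30, 230)) {
  if (!is_image_stack(stack) || stack$axis != "t")
    stop_cm("validation_error", "input must be an ImageStack with axis \"t\"")
  lapply(stack$frames, detect_spots, diameter = diameter,
         intensity_window = intensity_window)
}

# Globally optimal one-to-one matching between two point sets:
# maximises the number of pairs within max_dist and, among such
# matchings, minimises the total squared displacement. Returns an
# integer vector idx of length nrow(a); idx[i] = matched row of b or NA.
match_frame_pair <- function(a, b, max_dist) {
  na_ <- nrow(a); nb <- nrow(b)
  if (!na_ || !nb) return(rep(NA_integer_, na_))
  d2 <- outer(seq_len(na_), seq_len(nb), function(i, j)
    (a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2)
  assignment_min_cost(d2, d2 <= max_dist^2)
}

# maximum-cardinality, minimum-cost one-to-one assignment over the valid
# entries of a cost matrix (maximum-weight bipartite matching with
# cardinality-dominant weights); returns per-row match index or NA
assignment_min_cost <- function(cost, valid) {
  na_ <- nrow(cost); nb <- ncol(cost)
  if (!any(valid)) return(rep(NA_integer_, na_))
  ij <- which(valid, arr.ind = TRUE)
  big <- max(cost[valid]) * (min(na_, nb) + 2) + 1
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, na_), rep(TRUE, nb)),
    as.vector(t(cbind(ij[, 1], na_ + ij[, 2]))))
  igraph::E(g)$weight <- big - cost[valid]
  m <- igraph::max_bipartite_match(g)$matching
  idx <- m[seq_len(na_)] - na_
  idx[idx < 1 | is.na(idx)] <- NA_integer_
  as.integer(idx)
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment (minimum total
#' squared displacement among pairs within `max_dist`), followed by gap
#' closing: a track that ends at frame `f` may be joined to one that
#' starts at frame `f + g + 1` for `g = 1 .. max_gap` (ascending), when
#' the bridging displacement is at most `max_dist * (g + 1)`. Every
#' detection belongs to at most one track.
#'
#' @param spots list of per-frame spot data.frames
#'   (from [detect_spots_stack()] or equivalent).
#' @param max_dist maximum frame-to-frame jump in um (default 20).
#' @param max_gap maximum number of bridged missing frames (default 5).
#' @return data.frame with `track_id`, `frame` (1-based), `x_um`,
#'   `y_um`.
#' @export
link_tracks <- function(spots, max_dist = 20, max_gap = 5) {
  check_scalar_pos(max_dist, "max_dist")
  check_scalar_nonneg(max_gap, "max_gap")
  nf <- length(spots)
  det <- do.call(rbind, lapply(seq_len(nf), function(f) {
    s <- spots[[f]]
    if (is.null(s) || !nrow(s))
      return(data.frame(frame = integer(0), x_um = numeric(0),
                        y_um = numeric(0)))
    data.frame(frame = f, x_um = s$x_um, y_um = s$y_um)
  }))
  if (!nrow(det)) return(data.frame(track_id = integer(0), frame = integer(0),
                                    x_um = numeric(0), y_um = numeric(0)))
  det$track <- NA_integer_
  next_id <- 1L
  # pass 1: frame-to-frame assignment
  for (f in seq_len(nf)) {
    cur <- which(det$frame == f)
    if (!length(cur)) next
    unassigned <- is.na(det$track[cur])
    if (any(unassigned)) {
      det$track[cur[unassigned]] <-
        seq.int(next_id, length.out = sum(unassigned))
      next_id <- next_id + sum(unassigned)
    }
    if (f == nf) break
    nxt <- which(det$frame == f + 1L)
    if (!length(nxt)) next
    idx <- match_frame_pair(det[cur, ], det[nxt, ], max_dist)
    hit <- !is.na(idx)
    det$track[nxt[idx[hit]]] <- det$track[cur[hit]]
  }
  # pass 2: gap closing, ascending gap length; within each gap length
  # the end-to-start pairing is an optimal assignment, as in pass 1
  if (max_gap >= 1) {
    for (g in seq_len(max_gap)) {
      tr <- split(seq_len(nrow(det)), det$track)
      ends <- vapply(tr, function(i) i[which.max(det$frame[i])], integer(1))
      starts <- vapply(tr, function(i) i[which.min(det$frame[i])], integer(1))
      e_fr <- det$frame[ends]; s_fr <- det$frame[starts]
      pair_gate <- max_dist * (g + 1)
      d2 <- outer(seq_along(ends), seq_along(starts), function(i, j)
        (det$x_um[ends[i]] - det$x_um[starts[j]])^2 +
          (det$y_um[ends[i]] - det$y_um[starts[j]])^2)
      valid <- outer(e_fr, s_fr, function(e, s) s - e == g + 1L) &
        d2 <= pair_gate^2 &
        outer(names(ends), names(starts), `!=`)
      if (!any(valid)) next
      idx <- assignment_min_cost(d2, valid)
      for (e in which(!is.na(idx))) {
        from_id <- det$track[ends[e]]
        to_id <- det$track[starts[idx[e]]]
        if (from_id == to_id) next
        det$track[det$track == to_id] <- from_id
      }
    }
  }
  ids <- sort(unique(det$track))
  det$track_id <- match(det$track, ids)
  out <- det[order(det$track_id, det$frame),
             c("track_id", "frame", "x_um", "y_um")]
  rownames(out) <- NULL
  out
}

#' Mean speed of one track
#'
#' Mean over consecutive detections of Euclidean displacement divided by
#' elapsed time `(delta frame) * frame_interval`.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um` (one track).
#' @param frame_interval minutes per frame.
#' @return speed in um/min.
#' @export
track_speed <- function(track, frame_interval) {
  check_scalar_pos(frame_interval, "frame_interval")
  track <- track[order(track$frame), ]
  if (nrow(track) < 2)
    stop_cm("undefined_speed_error",
            "speed undefined for a single-detection track")
  dx <- diff(track$x_um); dy <- diff(track$y_um); df <- diff(track$frame)
  mean(sqrt(dx^2 + dy^2) / (df * frame_interval))
}

#' Track summary table
#'
#' @param tracks data.frame from [link_tracks()].
#' @param frame_interval minutes per frame.
#' @param min_detections tracks with fewer detections are dropped
#'   (default 2; speed is undefined below that).
#' @return data.frame with `track_id`, `n_detections`,
#'   `mean_speed_um_per_min`.
#' @export
summarize_tracks <- function(tracks, frame_interval, min_detections = 2L) {
  ids <- sort(unique(tracks$track_id))
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < min_detections) return(NULL)
    data.frame(track_id = id, n_detections = nrow(tr),
               mean_speed_um_per_min = track_speed(tr, frame_interval))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), n_detections = integer(0),
                      mean_speed_um_per_min = numeric(0))
  out
}

#' Confluence area above an intensity threshold
#'
#' Area occupied by cells, measured as the count of pixels strictly
#' above a (high) intensity threshold times the pixel area — the
#' standard thresholded-area proliferation read-out for a bright
#' cytoplasmic label.
#'
#' @param frame `ImageFrame`.
#' @param threshold intensity threshold in native units.
#' @return area in um^2.
#' @export
confluence_area <- function(frame, threshold) {
  sum(frame$pixels > threshold) * frame$pixel_size^2
}
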