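#' Stellate spheroid invasion pipeline
#'
#' Quantifies single stellate spheroids — a dense core with radiating
#' strands of invading cells — from one brightfield or fluorescence frame
#' per well. The pipeline mirrors classical image cytometry: grey
#' conversion, local background reduction, foreground thresholding, a
#' local-density image, and a three-zone decomposition (inner core /
#' outer core / periphery) from which the invasion read-outs are taken:
#' inner-core circularity (1 = round, least invasive), outer-core area
#' and peripheral invading-cell area.
#'
#' @name stellate_pipeline
NULL

#' Convert a frame to a single grey channel
#'
#' Unweighted mean of the channels, rounded half-up to preserve the
#' integer intensity scale; already-grey frames pass through unchanged.
#'
#' @param frame an [image_frame()] with 1-4 channels.
#' @return a grey `ImageFrame`.
#' @export
to_grey <- function(frame) {
  px <- frame$pixels
  if (length(dim(px)) == 2L) return(frame)
  nch <- dim(px)[3]
  if (nch < 1L || nch > 4L)
    stop_cm("validation_error", "expected 1-4 channels, got ", nch)
  g <- floor(apply(px, c(1, 2), mean) + 0.5)
  image_frame(g, bit_depth = frame$bit_depth,
              pixel_size = frame$pixel_size, channel = "grey")
}

#' Local background reduction (rolling-ball subtraction)
#'
#' Morphological white top-hat: a greyscale opening with a disc
#' structuring element of the given radius is subtracted from the image.
#' A flat or smoothly varying illumination field is removed exactly in
#' the interior (edges are handled by replicate padding) while objects
#' smaller than the ball keep their full amplitude. The ball radius must
#' comfortably exceed the objects of interest — a good rule is at least
#' three cell diameters — or the objects themselves are eroded.
#'
#' @param grey a grey `ImageFrame`.
#' @param ball_radius structuring-element radius in micrometres
#'   (default 50).
#' @return background-subtracted `ImageFrame` (non-negative).
#' @export
subtract_background <- function(grey, ball_radius = 50) {
  check_scalar_pos(ball_radius, "ball_radius")
  r_px <- floor(um_to_px(ball_radius, grey$pixel_size))
  if (r_px < 1L)
    stop_cm("validation_error",
            "ball_radius is smaller than one pixel at this calibration")
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  # EBImage greyscale morphology assumes intensities in [0, 1]
  mx <- 2^grey$bit_depth - 1
  p <- edge_pad(grey$pixels / mx, r_px)
  op <- as.matrix(EBImage::opening(EBImage::Image(p), brush)) * mx
  out <- pmax(grey$pixels - crop_pad(op, r_px), 0)
  image_frame(out, bit_depth = grey$bit_depth,
              pixel_size = grey$pixel_size, channel = grey$channel)
}

#' Foreground detection
#'
#' Pixels strictly above an automatic (Otsu) or fixed threshold on a
#' background-subtracted frame. The threshold actually applied is
#' attached as attribute `"threshold"` so batch runs can log it.
#'
#' @param grey background-subtracted `ImageFrame`.
#' @param method `"otsu"` or a single numeric fixed threshold.
#' @return logical matrix (`BinaryMask`) with attribute `"threshold"`.
#' @export
detect_foreground <- function(grey, method = "otsu") {
  t <- if (identical(method, "otsu")) {
    threshold_otsu(grey$pixels)
  } else if (is.numeric(method) && length(method) == 1L) {
    method
  } else stop_cm("validation_error", "method must be \"otsu\" or a number")
  mask <- grey$pixels > t
  attr(mask, "threshold") <- t
  mask
}

#' Local foreground density image
#'
#' Gaussian smoothing of the 0/1 foreground indicator with reflective
#' boundary handling; values lie in `[0, 1]` and measure the local
#' fraction of foreground, high inside the dense spheroid body and low
#' among scattered invading cells.
#'
#' @param foreground logical matrix.
#' @param sigma smoothing scale in micrometres (default 15).
#' @param pixel_size micrometres per pixel.
#' @return numeric matrix in `[0, 1]`.
#' @export
density_map <- function(foreground, sigma = 15, pixel_size = 1) {
  check_scalar_pos(sigma, "sigma")
  check_scalar_pos(pixel_size, "pixel_size")
  d <- gauss_blur(matrix(as.numeric(foreground), nrow(foreground)),
                  um_to_px(sigma, pixel_size))
  pmin(pmax(d, 0), 1)
}

#' Decompose a spheroid into inner core, outer core and periphery
#'
#' The inner core is the largest connected component of
#' `{density >= d_hi} & foreground`, hole-filled; the outer core is the
#' hole-filled largest component of `{density >= d_lo} & foreground`
#' minus the inner core; the periphery is the remaining foreground
#' (detached invading cells). Hole-filled pixels are absorbed into the
#' reported foreground so that the three zones are pairwise disjoint and
#' partition it exactly.
#'
#' @param foreground logical matrix from [detect_foreground()].
#' @param density density matrix from [density_map()].
#' @param d_hi,d_lo density cut-offs, `0 < d_lo < d_hi <= 1`
#'   (defaults 0.75 / 0.35).
#' @return a `SpheroidZones` list: `inner_core`, `outer_core`,
#'   `periphery`, `foreground`, `density`.
#' @export
split_zones <- function(foreground, density, d_hi = 0.75, d_lo = 0.35) {
  if (!(0 < d_lo && d_lo < d_hi && d_hi <= 1))
    stop_cm("validation_error", "need 0 < d_lo < d_hi <= 1")
  if (!any(density >= d_lo & foreground))
    stop_cm("no_spheroid_error",
            "no foreground pixel reaches density ", d_lo)
  hi <- largest_component(density >= d_hi & foreground)
  inner <- if (any(hi)) fill_holes(hi) else hi
  lo <- largest_component(density >= d_lo & foreground)
  core_lo <- fill_holes(lo)
  outer <- core_lo & !inner
  fg <- foreground | inner | core_lo
  periph <- fg & !inner & !outer
  structure(list(inner_core = unname(inner), outer_core = unname(outer),
                 periphery = periph, foreground = fg, density = density),
            class = "SpheroidZones")
}

#' Invasion read-outs of a zoned spheroid
#'
#' @param zones a `SpheroidZones` object from [split_zones()].
#' @param pixel_size micrometres per pixel.
#' @return a `StellateMetrics` list: `inner_circularity` (dimensionless,
#'   in `[0, 1]`; 1 = circular, least invasive), `inner_area`,
#'   `outer_area` and `peripheral_area` (um^2).
#' @export
stellate_metrics <- function(zones, pixel_size) {
  check_scalar_pos(pixel_size, "pixel_size")
  if (!any(zones$inner_core))
    stop_cm("undefined_circularity_error",
            "inner core is empty; circularity undefined")
  rm_ <- region_metrics(zones$inner_core, pixel_size)
  structure(list(
    inner_circularity = rm_$circularity,
    inner_area = sum(zones$inner_core) * pixel_size^2,
    outer_area = sum(zones$outer_core) * pixel_size^2,
    peripheral_area = sum(zones$periphery) * pixel_size^2),
    class = "StellateMetrics")
}

#' Run the full stellate pipeline on one frame
#'
#' Grey conversion, optional brightfield inversion (spheroids are darker
#' than the background in brightfield, and thresholding expects bright
#' objects), rolling-ball background reduction, foreground detection,
#' density image, zone split and metrics. An optional exclusion mask
#' (non-interactive stand-in for manual artefact correction) removes
#' pixels from the foreground before zoning.
#'
#' The background ball here defaults to 250 um, much larger than the
#' generic [subtract_background()] default: the structure of interest —
#' the spheroid core, hundreds of micrometres across — must roll
#' through untouched, so the ball has to exceed the core diameter while
#' staying below the illumination-artefact scale.
#'
#' @param frame input `ImageFrame`.
#' @param ball_radius,sigma,d_hi,d_lo pipeline parameters, see the
#'   stage functions.
#' @param invert invert intensities before thresholding; defaults to
#'   `TRUE` when the frame's channel is `"brightfield"`.
#' @param method threshold method for [detect_foreground()].
#' @param exclude optional logical matrix of pixels to exclude.
#' @return list with `metrics` (`StellateMetrics`), `zones`
#'   (`SpheroidZones`) and `threshold` (value used).
#' @export
analyze_stellate <- function(frame, ball_radius = 250, sigma = 15,
                             d_hi = 0.75, d_lo = 0.35,
                             invert = identical(frame$channel, "brightfield"),
                             method = "otsu", exclude = NULL) {
  g <- to_grey(frame)
  if (isTRUE(invert)) {
    mx <- 2^g$bit_depth - 1
    g <- image_frame(mx - g$pixels, g$bit_depth, g$pixel_size, g$channel)
  }
  bs <- subtract_background(g, ball_radius)
  fg <- detect_foreground(bs, method)
  thr <- attr(fg, "threshold")
  if (!is.null(exclude)) fg <- fg & !exclude
  dens <- density_map(fg, sigma, frame$pixel_size)
  zones <- split_zones(fg, dens, d_hi, d_lo)
  list(metrics = stellate_metrics(zones, frame$pixel_size),
       zones = zones, threshold = thr)
}
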