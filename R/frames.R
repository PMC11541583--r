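#' Calibrated image frame
#'
#' An `ImageFrame` is the package's unit of image data: a 2D (or, for
#' multi-channel originals, 3D with channels along the third dimension)
#' array of non-negative intensities together with the acquisition
#' calibration. Pixels are indexed `[row, col]` with the origin at the
#' top-left; `x` runs along columns and `y` along rows (0-based when
#' reported as coordinates), and physical coordinates are
#' `pixel index * pixel_size` micrometres.
#'
#' @param pixels numeric matrix (or 3D array, channels last) of
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, 8 or 16.
#' @param pixel_size micrometres per pixel (isotropic, > 0).
#' @param channel free-text channel label, e.g. `"brightfield"`,
#'   `"calcein"`, `"ethidium"`, `"mKO2"`.
#' @return An object of class `ImageFrame`.
#' @export
image_frame <- function(pixels, bit_depth = 16L, pixel_size = 1,
                        channel = "grey") {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop_cm("validation_error", "pixels must be a 2D matrix or 3D array")
  if (!bit_depth %in% c(8L, 16L))
    stop_cm("validation_error", "bit_depth must be 8 or 16")
  check_scalar_pos(pixel_size, "pixel_size")
  mx <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > mx)
    stop_cm("validation_error",
            "intensities must lie in [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size = pixel_size, channel = channel),
            class = "ImageFrame")
}

is_image_frame <- function(x) inherits(x, "ImageFrame")

#' Ordered image stack (z or t)
#'
#' @param frames list of [image_frame()] objects sharing dimensions,
#'   bit depth and pixel size.
#' @param axis `"z"` for focal series or `"t"` for time-lapse.
#' @param spacing micrometres between z-planes, or seconds between
#'   time points (> 0).
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(frames, axis = c("z", "t"), spacing = 1) {
  axis <- match.arg(axis)
  if (!length(frames)) stop_cm("validation_error", "stack needs >= 1 frame")
  if (!all(vapply(frames, is_image_frame, logical(1))))
    stop_cm("validation_error", "frames must be ImageFrame objects")
  d1 <- dim(frames[[1]]$pixels)
  same <- vapply(frames, function(f)
    identical(dim(f$pixels), d1) &&
      isTRUE(all.equal(f$pixel_size, frames[[1]]$pixel_size)), logical(1))
  if (!all(same))
    stop_cm("validation_error",
            "all frames must share dimensions and pixel_size")
  check_scalar_pos(spacing, "spacing")
  structure(list(frames = frames, axis = axis, spacing = spacing),
            class = "ImageStack")
}

is_image_stack <- function(x) inherits(x, "ImageStack")

#' @export
print.ImageFrame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageFrame %dx%d%s, %d-bit, %g um/px, channel '%s'\n",
              d[1], d[2],
              if (length(d) == 3L) sprintf("x%d", d[3]) else "",
              x$bit_depth, x$pixel_size, x$channel))
  invisible(x)
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("ImageStack of %d frames, axis '%s', spacing %g %s\n",
              length(x$frames), x$axis, x$spacing,
              if (x$axis == "z") "um" else "s"))
  invisible(x)
}

# -- masks -------------------------------------------------------------------

# A BinaryMask is a plain logical matrix; a LabelMask an integer matrix with
# 0 = background and objects labelled 1..K. Helpers below keep the label
# convention honest.

#' Relabel a label mask to contiguous labels 1..K
#'
#' @param labels integer matrix, 0 = background.
#' @return integer matrix with labels renumbered 1..K preserving order of
#'   first appearance of the original label values.
#' @export
relabel_mask <- function(labels) {
  u <- sort(unique(as.vector(labels)))
  u <- u[u > 0]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(u)) out[labels == u[i]] <- i
  out
}

# largest connected component of a logical mask (8-connected);
# empty mask stays empty. Alternate component labels are returned as an
# attribute so callers can log them.
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- lab == keep
  attr(out, "n_components") <- length(sizes)
  out
}

fill_holes <- function(mask) {
  as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
}
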