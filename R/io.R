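#' Read a TIFF image as a calibrated frame or stack
#'
#' Single-page files return an [image_frame()]; multi-page files return an
#' [image_stack()]. Intensities are read at native integer scale (no
#' normalisation). Calibration is supplied by the caller, never parsed from
#' TIFF tags: objective pixel sizes differ between instruments and TIFF
#' dialects encode them inconsistently, so the user-supplied value is the
#' one trusted (any tag value is ignored).
#'
#' @param path path to a TIFF file (8- or 16-bit grey, single or
#'   multi-page; RGB pages are returned as 3D-pixel frames).
#' @param pixel_size micrometres per pixel.
#' @param channel channel label recorded on the frame(s).
#' @param axis for multi-page files, `"z"` or `"t"`.
#' @param spacing for multi-page files, micrometres (z) or seconds (t)
#'   between pages.
#' @return An `ImageFrame` or `ImageStack`.
#' @export
read_image <- function(path, pixel_size, channel = "grey",
                       axis = "z", spacing = 1) {
  check_scalar_pos(pixel_size, "pixel_size")
  if (!file.exists(path))
    stop_cm("format_error", "file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e)
      stop_cm("format_error", "cannot read TIFF '", path, "': ",
              conditionMessage(e)))
  if (!length(pages)) stop_cm("format_error", "empty TIFF: ", path)
  bits <- if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
  mk <- function(p) image_frame(p, bit_depth = bits,
                                pixel_size = pixel_size, channel = channel)
  if (length(pages) == 1L) return(mk(pages[[1]]))
  image_stack(lapply(pages, mk), axis = axis, spacing = spacing)
}

#' Write a frame or stack to TIFF
#'
#' Pixels are written at the frame's declared bit depth; a
#' write/[read_image()] round-trip is bit-identical.
#'
#' @param x `ImageFrame` or `ImageStack`.
#' @param path output path.
#' @export
write_image <- function(x, path) {
  frames <- if (is_image_stack(x)) x$frames else list(x)
  bits <- frames[[1]]$bit_depth
  mx <- 2^bits - 1
  planes <- lapply(frames, function(f) round(f$pixels) / mx)
  ok <- tryCatch(
    tiff::writeTIFF(if (length(planes) == 1L) planes[[1]] else planes,
                    path, bits.per.sample = bits),
    error = function(e)
      stop_cm("io_error", "cannot write TIFF '", path, "': ",
              conditionMessage(e)))
  invisible(ok)
}

#' Write metric rows to CSV
#'
#' Plain UTF-8 CSV with a header row, dot decimal separator and no row
#' names; an empty record set produces a header-only file. A parse-back
#' with [read_metrics()] reproduces values to at least 6 significant
#' digits (numbers are written at full double precision).
#'
#' @param records a data.frame of metric rows (possibly 0-row).
#' @param path output path.
#' @export
write_metrics <- function(records, path) {
  if (!is.data.frame(records))
    stop_cm("validation_error", "records must be a data.frame")
  ok <- tryCatch({
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    write.csv(records, con, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop_cm("io_error", "cannot write CSV '", path, "': ",
            conditionMessage(e)))
  invisible(ok)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
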