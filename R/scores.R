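#' Caliper tumour volume
#'
#' Ellipsoid-style volume from two perpendicular caliper dimensions:
#' `V = pi/6 * (d1 * d2)^(3/2)` with `d1`, `d2` in mm and `V` in mm^3
#' (the product in mm^2 raised to 3/2 is dimensionally a volume). The
#' formula is symmetric in its arguments and homogeneous of degree 3:
#' scaling both dimensions by `k` scales the volume by `k^3`. For
#' `d1 = d2 = d` it reduces to the sphere volume `pi/6 * d^3`.
#'
#' @param d1,d2 perpendicular tumour dimensions in mm (vectorised).
#' @return volume(s) in mm^3.
#' @export
tumour_volume <- function(d1, d2) {
  if (!is.numeric(d1) || !is.numeric(d2) || any(d1 <= 0) || any(d2 <= 0))
    stop_cm("validation_error", "caliper dimensions must be positive")
  pi / 6 * (d1 * d2)^(3 / 2)
}

#' Composite immunohistochemistry staining score
#'
#' Sum of a percent-positive bin and a staining-intensity grade. The
#' percent-positive scale bins the fraction of positively stained cells
#' as 0 (0%), 1 ((0, 25]%), 2 ((25, 50]%), 3 ((50, 75]%) and
#' 4 ((75, 100]%); the bins are right-closed so every percentage has
#' exactly one bin. Intensity is graded 0 (none), 1 (slight),
#' 2 (moderate), 3 (strong). The total ranges 0-7.
#'
#' @param percent_positive percentage of positive cells, in `[0, 100]`
#'   (vectorised).
#' @param intensity_grade integer grade in 0-3 (vectorised).
#' @return data.frame with `percent_positive`, `positivity_bin`,
#'   `intensity_grade`, `total`.
#' @export
ihc_score <- function(percent_positive, intensity_grade) {
  if (any(percent_positive < 0 | percent_positive > 100) ||
      anyNA(percent_positive))
    stop_cm("validation_error", "percent_positive must be in [0, 100]")
  if (!all(intensity_grade %in% 0:3))
    stop_cm("validation_error", "intensity_grade must be 0, 1, 2 or 3")
  bin <- findInterval(percent_positive, c(0, 25, 50, 75),
                      left.open = TRUE)  # (0,25] -> 1 ... (75,100] -> 4
  data.frame(percent_positive = percent_positive,
             positivity_bin = as.integer(bin),
             intensity_grade = as.integer(intensity_grade),
             total = as.integer(bin + intensity_grade))
}

#' Normalise values to a control mean
#'
#' Elementwise `value / control_mean`, the generic
#' relative-to-control normalisation used across assays.
#'
#' @param values numeric vector.
#' @param control_mean scalar, non-zero.
#' @return vector of ratios.
#' @export
relative_to_control <- function(values, control_mean) {
  if (!is.numeric(control_mean) || length(control_mean) != 1L ||
      control_mean == 0 || !is.finite(control_mean))
    stop_cm("undefined_ratio_error",
            "control mean must be a non-zero finite scalar")
  values / control_mean
}
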