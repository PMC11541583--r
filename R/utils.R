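#' @importFrom stats dnorm rnorm rpois runif median
#' @importFrom utils write.csv read.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cm <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(class, "cytomorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_cm("validation_error", name, " must be a single positive number")
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_cm("validation_error", name, " must be a single non-negative number")
  invisible(x)
}

# µm -> pixels for the given calibration
um_to_px <- function(um, pixel_size) um / pixel_size

# matrix shifted by (dr, dc), zero-filled at the borders
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(vector(typeof(m), 1L), nr, nc)
  rs <- (1:nr) - dr; cs <- (1:nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# mirror-pad a matrix by `pad` pixels on every side
mirror_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- min(pad, nr - 1L, nc - 1L)
  ri <- c(seq(pad + 1L, 2L, by = -1L), 1:nr, seq(nr - 1L, nr - pad, by = -1L))
  ci <- c(seq(pad + 1L, 2L, by = -1L), 1:nc, seq(nc - 1L, nc - pad, by = -1L))
  m[ri, ci, drop = FALSE]
}

# replicate-pad (edge extension)
edge_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, pad), 1:nr, rep(nr, pad))
  ci <- c(rep(1L, pad), 1:nc, rep(nc, pad))
  m[ri, ci, drop = FALSE]
}

crop_pad <- function(m, pad) {
  m[(pad + 1L):(nrow(m) - pad), (pad + 1L):(ncol(m) - pad), drop = FALSE]
}

# Gaussian blur with mirror (reflective) boundary handling.
# Kernel is normalised, so a constant image maps to itself.
gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k1 <- dnorm(seq(-half, half), sd = sigma_px)
  k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  p <- mirror_pad(m, half)
  out <- EBImage::filter2(EBImage::Image(p), kern)
  crop_pad(as.matrix(out), min(half, nrow(m) - 1L, ncol(m) - 1L))
}

# greyscale local-maximum filter over a (2h+1) square window
# (EBImage greyscale dilation clamps to [0, 1], so rescale around it)
max_filter <- function(m, half) {
  if (half < 1L) return(m)
  rng <- range(m)
  if (rng[1] == rng[2]) return(m)
  m01 <- (m - rng[1]) / (rng[2] - rng[1])
  br <- EBImage::makeBrush(2L * half + 1L, shape = "box")
  as.matrix(EBImage::dilate(EBImage::Image(m01), br)) *
    (rng[2] - rng[1]) + rng[1]
}
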