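#' Otsu threshold with a lowest-threshold tie break
#'
#' Maximises between-class variance over a binned intensity histogram.
#' When several thresholds achieve the optimum (multi-modal or plateaued
#' histograms) the lowest is returned, which favours inclusion of dim
#' invading cells in downstream masks.
#'
#' @param x numeric matrix or vector of intensities.
#' @param levels number of histogram bins.
#' @return threshold value on the intensity scale; pixels strictly above
#'   it are foreground.
#' @export
threshold_otsu <- function(x, levels = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop_cm("degenerate_histogram_error",
            "constant image: Otsu threshold is undefined")
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which(sb == max(sb))[1]  # lowest optimal threshold
  edges[k + 1L]
}

# scale-normalised Laplacian-of-Gaussian kernel; negative peak at the
# centre, so bright blobs of radius ~ sigma*sqrt(2) give strongly negative
# responses. We return -LoG so blob responses are positive maxima.
log_kernel <- function(sigma_px) {
  half <- max(2L, ceiling(4 * sigma_px))
  g <- expand.grid(x = -half:half, y = -half:half)
  r2 <- g$x^2 + g$y^2
  s2 <- sigma_px^2
  k <- (r2 - 2 * s2) / (s2^2) * exp(-r2 / (2 * s2))
  k <- k - mean(k)                       # zero response to flat fields
  matrix(-k * s2, 2L * half + 1L)        # scale-normalised, sign-flipped
}

# Blob candidates: local maxima of the -LoG response above a response
# floor, separated by at least min_sep_px. Returns 1-based (row, col)
# pixel positions ordered by decreasing response.
log_maxima <- function(pixels, sigma_px, min_sep_px,
                       response_floor_rel = 0.05) {
  kern <- log_kernel(sigma_px)
  half <- (nrow(kern) - 1L) / 2L
  pm <- mirror_pad(pixels, half)
  resp <- crop_pad(as.matrix(EBImage::filter2(EBImage::Image(pm), kern)),
                   min(half, nrow(pixels) - 1L, ncol(pixels) - 1L))
  sep <- max(1L, floor(min_sep_px / 2))
  mx <- max_filter(resp, sep)
  floor_abs <- response_floor_rel * max(resp, 0)
  tol <- 1e-8 * max(abs(resp))   # max filter round-trips through [0,1]
  cand <- which(resp >= mx - tol & resp > floor_abs & resp > 0,
                arr.ind = TRUE)
  if (!nrow(cand)) return(cbind(row = integer(0), col = integer(0)))
  ord <- order(-resp[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  # enforce min separation between accepted maxima (plateaus, near-ties)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
    if (all(d2 >= min_sep_px^2)) keep[i] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

# sub-pixel refinement: intensity-weighted centroid of the
# background-subtracted window around a peak. Returns (row, col) doubles.
refine_centroid <- function(pixels, row, col, half) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  r0 <- max(1L, row - half); r1 <- min(nr, row + half)
  c0 <- max(1L, col - half); c1 <- min(nc, col + half)
  w <- pixels[r0:r1, c0:c1, drop = FALSE]
  w <- w - min(w)
  s <- sum(w)
  if (s <= 0) return(c(row, col))
  rows <- r0:r1; cols <- c0:c1
  c(sum(rowSums(w) * rows) / s, sum(colSums(w) * cols) / s)
}
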