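# Rasterised reference shapes and small oracles shared across tests.

raster_disc <- function(n = 256, r = 100, ctr = (n + 1) / 2) {
  g <- expand.grid(x = 1:n, y = 1:n)
  matrix((g$x - ctr)^2 + (g$y - ctr)^2 <= r^2, n)
}

raster_square <- function(n = 256, side = 100) {
  m <- matrix(FALSE, n, n)
  o <- floor((n - side) / 2)
  m[(o + 1):(o + side), (o + 1):(o + side)] <- TRUE
  m
}

raster_star <- function(n = 256, arm_w = 21, arm_l = 200) {
  m <- matrix(FALSE, n, n)
  c0 <- (n - arm_w) %/% 2; a0 <- (n - arm_l) %/% 2
  m[(c0 + 1):(c0 + arm_w), (a0 + 1):(a0 + arm_l)] <- TRUE
  m[(a0 + 1):(a0 + arm_l), (c0 + 1):(c0 + arm_w)] <- TRUE
  m
}

theta_mask <- function(n = 200, r_out = 64, r_in = 56, bar_hw = 4) {
  ctr <- (n + 1) / 2
  gx <- matrix(rep(1:n, each = n), n); gy <- matrix(rep(1:n, n), n)
  r <- sqrt((gx - ctr)^2 + (gy - ctr)^2)
  (r <= r_out & r >= r_in) | (abs(gy - ctr) <= bar_hw & r <= r_out)
}

voxel_ball <- function(r = 20) {
  d <- 2 * r + 9; ctr <- (d + 1) / 2
  out <- array(FALSE, c(d, d, d))
  for (z in 1:d) {
    r2 <- r^2 - (z - ctr)^2
    if (r2 > 0)
      out[, , z] <- outer((1:d) - ctr, (1:d) - ctr,
                          function(a, b) a^2 + b^2) <= r2
  }
  out
}

voxel_cube <- function(side = 40, pad = 5) {
  d <- side + 2 * pad
  out <- array(FALSE, c(d, d, d))
  out[(pad + 1):(pad + side), (pad + 1):(pad + side),
      (pad + 1):(pad + side)] <- TRUE
  out
}

# symmetric difference of two masks restricted to outside the 1-pixel
# boundary band of the reference mask; empty means agreement within band
outside_boundary_band <- function(mask, ref) {
  k <- matrix(1, 3, 3)
  dil <- as.matrix(EBImage::dilate(EBImage::Image(ref), k)) > 0
  ero <- as.matrix(EBImage::erode(EBImage::Image(ref), k)) > 0
  (mask & !dil) | (!mask & ero)
}

# Exhaustive minimum-cost, maximum-cardinality one-to-one matching
# between point sets a and b (data.frames with x_um, y_um), gated at
# max_dist. Returns list(n_matched, cost). Feasible only for tiny sets.
brute_force_match <- function(a, b, max_dist) {
  na_ <- nrow(a); nb <- nrow(b)
  best <- list(n = -1L, cost = Inf)
  d2 <- if (na_ && nb)
    outer(seq_len(na_), seq_len(nb), function(i, j)
      (a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2)
  else matrix(numeric(0), na_, nb)
  recurse <- function(i, used, n, cost) {
    if (i > na_) {
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, n, cost)          # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (used[j] || d2[i, j] > max_dist^2) next
      used[j] <- TRUE
      recurse(i + 1L, used, n + 1L, cost + d2[i, j])
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nb), 0L, 0)
  best
}

# cost of a matching produced by match_frame_pair
matching_cost <- function(a, b, idx) {
  hit <- !is.na(idx)
  list(n = sum(hit),
       cost = sum((a$x_um[hit] - b$x_um[idx[hit]])^2 +
                    (a$y_um[hit] - b$y_um[idx[hit]])^2))
}
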