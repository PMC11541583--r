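#' 3D surface morphometry of a segmented cell
#'
#' Volume, surface area and sphericity of a 3D binary mask. Volume is
#' the exact voxel count times the voxel volume. Surface area is
#' measured on an isosurface mesh: the binary mask is lightly smoothed
#' (3D Gaussian) and triangulated at the 0.5 level by marching
#' tetrahedra; naive voxel-face counting would overestimate the area of
#' a sphere by a factor of about 1.5, while the isosurface mesh is
#' accurate to a few percent. The smoothing scale (default sigma = 0.65
#' voxels) trades the staircase inflation of curved surfaces against
#' the edge rounding of polyhedral ones; both residual biases are below
#' about 3 percent for objects a few tens of voxels across. Sphericity
#' is `psi = pi^(1/3) * (6 V)^(2/3) / A`, 1 for a ball, clamped to
#' `[0, 1]`.
#'
#' @param mask3d 3D logical (or 0/1) array.
#' @param voxel_size voxel edge lengths in um, length 1 (isotropic) or
#'   3 `(dx, dy, dz)`.
#' @param smooth_sigma pre-meshing Gaussian scale in voxels.
#' @return a `SurfaceMorphometry` list: `volume_um3`,
#'   `surface_area_um2`, `sphericity`.
#' @export
surface_morphometry <- function(mask3d, voxel_size = 1,
                                smooth_sigma = 0.65) {
  if (length(dim(mask3d)) != 3L)
    stop_cm("validation_error", "mask3d must be a 3D array")
  if (!any(mask3d != 0))
    stop_cm("validation_error", "empty mask: morphometry undefined")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_cm("validation_error", "voxel_size must be 1 or 3 positive values")
  m <- array(as.numeric(mask3d != 0), dim(mask3d))
  vol <- sum(m) * prod(voxel_size)
  sm <- gauss_blur3d(pad_array3d(m, 3L), sigma = smooth_sigma)
  area <- marching_tetrahedra_area(sm, iso = 0.5, scale = voxel_size)
  psi <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  structure(list(volume_um3 = vol, surface_area_um2 = area,
                 sphericity = min(1, max(0, psi))),
            class = "SurfaceMorphometry")
}

pad_array3d <- function(a, p) {
  d <- dim(a)
  out <- array(0, d + 2L * p)
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- a
  out
}

# separable 3D Gaussian blur; borders are zero-padded, which is the
# correct continuation for a mask embedded in empty space
gauss_blur3d <- function(a, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma); k <- k / sum(k)
  d <- dim(a)
  conv_along <- function(x, dim_i) {
    perm <- switch(dim_i, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(x, perm)
    dd <- dim(ap)
    mat <- matrix(ap, nrow = dd[1])
    n <- dd[1]
    out <- matrix(0, n, ncol(mat))
    for (o in seq(-half, half)) {
      w <- k[o + half + 1L]
      src <- (1:n) - o
      okr <- src >= 1 & src <= n
      out[okr, ] <- out[okr, ] + w * mat[src[okr], ]
    }
    ap2 <- array(out, dd)
    aperm(ap2, order(perm))
  }
  for (i in 1:3) a <- conv_along(a, i)
  a
}

# total isosurface area by marching tetrahedra on the cube grid; each
# cube cell is split into 6 tetrahedra around the 0-6 diagonal.
marching_tetrahedra_area <- function(vol, iso = 0.5, scale = c(1, 1, 1)) {
  d <- dim(vol)
  # candidate cells: those whose 8 corners straddle iso
  inb <- vol > iso
  cs <- inb[-d[1], -d[2], -d[3]] + inb[-1, -d[2], -d[3]] +
        inb[-d[1], -1, -d[3]]   + inb[-1, -1, -d[3]] +
        inb[-d[1], -d[2], -1]   + inb[-1, -d[2], -1] +
        inb[-d[1], -1, -1]      + inb[-1, -1, -1]
  cand <- which(cs > 0 & cs < 8, arr.ind = TRUE)
  if (!nrow(cand)) return(0)
  # cube corner offsets, standard vertex order
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
                c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))
  interp <- function(p1, p2, v1, v2) {
    t <- (iso - v1) / (v2 - v1)
    p1 + t * (p2 - p1)
  }
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    sqrt(sum(cr^2)) / 2
  }
  total <- 0
  for (ci in seq_len(nrow(cand))) {
    base <- cand[ci, ]
    vals <- numeric(8); pts <- matrix(0, 8, 3)
    for (k in 1:8) {
      idx <- base + corner[k, ]
      vals[k] <- vol[idx[1], idx[2], idx[3]]
      pts[k, ] <- (idx - 1) * scale
    }
    for (tt in 1:6) {
      vi <- tets[tt, ]
      v <- vals[vi]; p <- pts[vi, , drop = FALSE]
      inside <- v > iso
      ni <- sum(inside)
      if (ni == 0 || ni == 4) next
      if (ni == 1 || ni == 3) {
        lone <- if (ni == 1) which(inside) else which(!inside)
        rest <- setdiff(1:4, lone)
        q1 <- interp(p[lone, ], p[rest[1], ], v[lone], v[rest[1]])
        q2 <- interp(p[lone, ], p[rest[2], ], v[lone], v[rest[2]])
        q3 <- interp(p[lone, ], p[rest[3], ], v[lone], v[rest[3]])
        total <- total + tri_area(q1, q2, q3)
      } else {
        ins <- which(inside); outs <- which(!inside)
        q1 <- interp(p[ins[1], ], p[outs[1], ], v[ins[1]], v[outs[1]])
        q2 <- interp(p[ins[1], ], p[outs[2], ], v[ins[1]], v[outs[2]])
        q3 <- interp(p[ins[2], ], p[outs[1], ], v[ins[2]], v[outs[1]])
        q4 <- interp(p[ins[2], ], p[outs[2], ], v[ins[2]], v[outs[2]])
        total <- total + tri_area(q1, q2, q3) + tri_area(q3, q2, q4)
      }
    }
  }
  total
}
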