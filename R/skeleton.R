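# Topological skeletonization and skeleton-graph extraction.
#
# thin_mask(): Zhang-Suen parallel thinning followed by a sequential
# minimal-thinning pass that deletes remaining simple non-endpoint pixels
# (single foreground run among the 8 neighbours). The pass removes the
# staircase redundancies Zhang-Suen leaves on curved lines, so that line
# interior pixels have exactly two skeleton neighbours.

thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- if (step == 1) (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
              else           (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  # Sequential minimal-thinning: delete simple, non-endpoint pixels until
  # none remain. Simplicity is tested with the Yokoi connectivity number
  # for 8-connected foreground (C == 1); this removes the staircase and
  # two-pixel-wide diagonal braids that parallel thinning leaves behind
  # without ever changing topology.
  nbr_off <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                   c(0, -1), c(1, -1), c(1, 0), c(1, 1))  # E NE N NW W SW S SE
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (ii in which(m == 1)) {
      r0 <- ((ii - 1) %% nr) + 1; c0 <- ((ii - 1) %/% nr) + 1
      if (r0 == 1 || c0 == 1 || r0 == nr || c0 == nc) next
      x <- m[cbind(r0 + nbr_off[, 1], c0 + nbr_off[, 2])]
      B <- sum(x)
      if (B < 2) next
      b <- 1L - x
      cn <- 0L
      for (k in c(1L, 3L, 5L, 7L)) {
        k1 <- (k %% 8L) + 1L; k2 <- (k1 %% 8L) + 1L
        cn <- cn + b[k] - b[k] * b[k1] * b[k2]
      }
      if (cn == 1L) { m[ii] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

skeleton_neighbour_count <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk))
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) s <- s + shift_mat(m, dr, dc)
  s
}

# Trace the skeleton into node clusters and pixel-path segments.
# Node pixels are skeleton pixels with != 2 neighbours; 8-adjacent node
# pixels are merged into one cluster. Segments run between clusters with
# 8-connected geodesic length (1 per axial step, sqrt(2) per diagonal).
# Pure cycles (closed loops with no node pixel) become self-loop
# segments on an anonymous degree-2 node.
trace_skeleton <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  nbr_off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  Bc <- skeleton_neighbour_count(sk)
  node_px <- sk & Bc != 2
  labm <- as.matrix(EBImage::bwlabel(EBImage::Image(node_px)))
  nclust <- max(labm)
  step_cost <- function(a, b)
    if (a[1] != b[1] && a[2] != b[2]) sqrt(2) else 1

  from <- integer(0); to <- integer(0); len <- numeric(0)
  path_key <- character(0)
  used <- matrix(FALSE, nr, nc)
  direct_seen <- character(0)

  for (cid in seq_len(nclust)) {
    px <- which(labm == cid, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) for (k in 1:8) {
      r <- px[i, 1] + nbr_off[k, 1]; c <- px[i, 2] + nbr_off[k, 2]
      if (r < 1 || c < 1 || r > nr || c > nc || !sk[r, c]) next
      lab_n <- labm[r, c]
      if (lab_n != 0 && lab_n != cid) {
        key <- paste(min(cid, lab_n), max(cid, lab_n), sep = "-")
        if (!key %in% direct_seen) {
          direct_seen <- c(direct_seen, key)
          from <- c(from, cid); to <- c(to, lab_n)
          len <- c(len, step_cost(px[i, ], c(r, c)))
          path_key <- c(path_key, key)
        }
      } else if (lab_n == 0 && !used[r, c]) {
        cur <- c(r, c); prev <- px[i, ]
        plen <- step_cost(prev, cur)
        first_id <- (cur[2] - 1) * nr + cur[1]
        last_id <- first_id; npath <- 1L
        dest <- NA_integer_
        repeat {
          used[cur[1], cur[2]] <- TRUE
          cand_node <- NULL; cand_path <- NULL
          for (k2 in 1:8) {
            r2 <- cur[1] + nbr_off[k2, 1]; c2 <- cur[2] + nbr_off[k2, 2]
            if (r2 < 1 || c2 < 1 || r2 > nr || c2 > nc || !sk[r2, c2]) next
            if (r2 == prev[1] && c2 == prev[2]) next
            if (labm[r2, c2] != 0) {
              if (labm[r2, c2] != cid) { cand_node <- c(r2, c2); break }
              if (is.null(cand_node)) cand_node <- c(r2, c2)
            } else if (!used[r2, c2] && is.null(cand_path)) {
              cand_path <- c(r2, c2)
            }
          }
          # avoid snapping straight back onto the origin cluster on the
          # first step when the path genuinely continues
          if (!is.null(cand_node) &&
              !(labm[cand_node[1], cand_node[2]] == cid && npath == 1L &&
                !is.null(cand_path))) {
            plen <- plen + step_cost(cur, cand_node)
            dest <- labm[cand_node[1], cand_node[2]]
            break
          }
          if (is.null(cand_path)) break  # dead end
          plen <- plen + step_cost(cur, cand_path)
          prev <- cur; cur <- cand_path
          last_id <- (cur[2] - 1) * nr + cur[1]; npath <- npath + 1L
        }
        key <- paste(min(first_id, last_id), max(first_id, last_id),
                     npath, sep = ":")
        if (!key %in% path_key) {
          from <- c(from, cid); to <- c(to, dest)
          len <- c(len, plen)
          path_key <- c(path_key, key)
        }
      }
    }
  }
  # anonymous pure cycles
  extra_nodes <- 0L
  remaining <- sk & labm == 0 & !used
  while (any(remaining)) {
    start <- which(remaining, arr.ind = TRUE)[1, ]
    cur <- start; prev <- c(-1L, -1L); plen <- 0
    repeat {
      remaining[cur[1], cur[2]] <- FALSE
      used[cur[1], cur[2]] <- TRUE
      nxt <- NULL
      for (k in 1:8) {
        r2 <- cur[1] + nbr_off[k, 1]; c2 <- cur[2] + nbr_off[k, 2]
        if (r2 < 1 || c2 < 1 || r2 > nr || c2 > nc || !sk[r2, c2]) next
        if (r2 == prev[1] && c2 == prev[2]) next
        if (remaining[r2, c2]) { nxt <- c(r2, c2); break }
        if (r2 == start[1] && c2 == start[2] && plen > 2) nxt <- "close"
      }
      if (is.null(nxt)) break
      if (identical(nxt, "close")) { plen <- plen + step_cost(cur, start); break }
      plen <- plen + step_cost(cur, nxt)
      prev <- cur; cur <- nxt
    }
    if (plen > 0) {
      extra_nodes <- extra_nodes + 1L
      id <- nclust + extra_nodes
      from <- c(from, id); to <- c(to, id); len <- c(len, plen)
    }
  }

  centres <- if (nclust > 0) {
    t(vapply(seq_len(nclust), function(i) {
      p <- which(labm == i, arr.ind = TRUE)
      c(mean(p[, 1]), mean(p[, 2]))
    }, numeric(2)))
  } else matrix(numeric(0), ncol = 2)
  if (extra_nodes > 0)
    centres <- rbind(centres, matrix(NA_real_, extra_nodes, 2))

  list(n_nodes = nclust + extra_nodes,
       cycle_nodes = if (extra_nodes) (nclust + 1L):(nclust + extra_nodes)
                     else integer(0),
       edges = data.frame(from = from, to = to, len = len),
       centres = centres)
}

# Simplify the traced graph: prune short spur branches, contract
# pass-through (degree-2) nodes, and fuse junction pairs joined by
# segments shorter than fuse_len (thick-junction splitting artefacts of
# thinning). All lengths in pixels here; caller scales to um.
simplify_skeleton_graph <- function(gr, prune_px, fuse_px) {
  edges <- gr$edges
  alive <- rep(TRUE, gr$n_nodes)
  cycle_node <- seq_len(gr$n_nodes) %in% gr$cycle_nodes
  merged_into <- seq_len(gr$n_nodes)

  deg <- function() {
    d <- numeric(gr$n_nodes)
    if (nrow(edges)) {
      t1 <- table(factor(edges$from, levels = seq_len(gr$n_nodes)))
      t2 <- table(factor(edges$to, levels = seq_len(gr$n_nodes)))
      d <- as.numeric(t1) + as.numeric(t2)
    }
    d
  }

  repeat {
    changed <- FALSE
    # artefact self-loops too short to enclose a face
    tiny <- edges$from == edges$to & edges$len < fuse_px
    if (any(tiny)) { edges <- edges[!tiny, , drop = FALSE]; changed <- TRUE }
    d <- deg()
    # drop NA-endpoint stubs of zero interest (open path to nowhere is an
    # extremity; give it a fresh node id so degree bookkeeping works)
    if (any(is.na(edges$to))) {
      for (i in which(is.na(edges$to))) {
        gr$n_nodes <- gr$n_nodes + 1L
        edges$to[i] <- gr$n_nodes
        alive <- c(alive, TRUE); cycle_node <- c(cycle_node, FALSE)
        gr$centres <- rbind(gr$centres, c(NA_real_, NA_real_))
      }
      d <- deg(); changed <- TRUE
    }
    # prune: leaf edges shorter than prune_px
    if (nrow(edges)) {
      leaf <- (d[edges$from] == 1 | d[edges$to] == 1) &
        edges$from != edges$to & edges$len < prune_px
      if (any(leaf)) { edges <- edges[!leaf, , drop = FALSE]; changed <- TRUE }
    }
    d <- deg()
    # contract a degree-2 pass-through node (not an anonymous cycle node)
    v <- which(d == 2 & alive & !cycle_node)
    contracted <- FALSE
    for (vi in v) {
      ei <- which(edges$from == vi | edges$to == vi)
      if (length(ei) != 2L) next          # one self-loop: leave as cycle
      e1 <- edges[ei[1], ]; e2 <- edges[ei[2], ]
      a <- if (e1$from == vi) e1$to else e1$from
      b <- if (e2$from == vi) e2$to else e2$from
      edges <- edges[-ei, , drop = FALSE]
      edges <- rbind(edges,
                     data.frame(from = min(a, b), to = max(a, b),
                                len = e1$len + e2$len))
      alive[vi] <- FALSE
      contracted <- TRUE; changed <- TRUE
      break
    }
    if (contracted) next
    # fuse: short junction-junction edges (split thick junctions)
    d <- deg()
    if (nrow(edges)) {
      short <- which(edges$len < fuse_px & edges$from != edges$to &
                       d[edges$from] >= 3 & d[edges$to] >= 3)
      if (length(short)) {
        e <- edges[short[1], ]
        keep <- min(e$from, e$to); drop <- max(e$from, e$to)
        edges <- edges[-short[1], , drop = FALSE]
        edges$from[edges$from == drop] <- keep
        edges$to[edges$to == drop] <- keep
        # self-loops created by the fusion that are just artefact triangles
        tiny_loop <- edges$from == edges$to & edges$len < fuse_px
        edges <- edges[!tiny_loop, , drop = FALSE]
        alive[drop] <- FALSE
        if (!all(is.na(gr$centres[c(keep, drop), 1])))
          gr$centres[keep, ] <- colMeans(gr$centres[c(keep, drop), ,
                                                    drop = FALSE], na.rm = TRUE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rownames(edges) <- NULL
  list(edges = edges, alive = alive, cycle_node = cycle_node,
       centres = gr$centres, n_nodes = gr$n_nodes)
}
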