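#' Endothelial tube-network quantification
#'
#' Measures capillary-like networks formed by endothelial cells on
#' basement-membrane matrix: the binarised network is reduced to a
#' one-pixel topological skeleton, the skeleton to a graph of nodes
#' (extremities, junctions) and segments, and the graph to the six
#' read-outs behind the angiogenesis index — junctions, master
#' junctions, master segments, total master-segment length, meshes and
#' total mesh area.
#'
#' @name tube_graph
NULL

#' Binarise a tube-network image
#'
#' Rolling-ball background subtraction, thresholding and small-object
#' removal, as in the spheroid pipeline.
#'
#' @param frame `ImageFrame`.
#' @param ball_radius background ball radius in um (default 50).
#' @param method `"otsu"` or a fixed numeric threshold.
#' @param min_object_area components smaller than this (um^2) are
#'   removed; 0 disables the filter.
#' @return logical mask.
#' @export
binarize_network <- function(frame, ball_radius = 50, method = "otsu",
                             min_object_area = 100) {
  bs <- subtract_background(to_grey(frame), ball_radius)
  mask <- detect_foreground(bs, method)
  thr <- attr(mask, "threshold")
  if (min_object_area > 0) {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0]) * frame$pixel_size^2
      mask <- matrix(lab %in% which(areas >= min_object_area) & lab > 0,
                     nrow(lab))
    }
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Extract the tube network graph from a binary mask
#'
#' The mask is thinned to a one-pixel 8-connected skeleton; skeleton
#' pixels with a neighbour count other than two become nodes (adjacent
#' node pixels merge into one node), and segments are traced between
#' nodes with 8-connected geodesic length (1 per axial step, sqrt(2)
#' per diagonal, times `pixel_size`). Branch segments ending at an
#' extremity shorter than `prune_len` are pruned iteratively; junction
#' pairs joined by a segment shorter than `fuse_len` are fused (thick
#' junctions split into nearby Y-pairs during thinning). Classification:
#' a master segment joins two junction-class nodes (degree >= 3); a
#' master junction touches at least one master segment. Meshes are the
#' interior faces fully enclosed by the skeleton (background components
#' not touching the image border), with pixel-count areas.
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param prune_len spur-pruning length in um (default 10).
#' @param fuse_len junction-fusion length in um (default `prune_len`).
#' @return a `TubeNetwork` list: `nodes` (x_um, y_um, degree, class),
#'   `segments` (from, to, length_um, class), `meshes` (area_um2),
#'   `skeleton` (logical matrix), `n_components`.
#' @export
skeleton_graph <- function(mask, pixel_size = 1, prune_len = 10,
                           fuse_len = prune_len) {
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_nonneg(prune_len, "prune_len")
  check_scalar_nonneg(fuse_len, "fuse_len")
  empty <- list(
    nodes = data.frame(x_um = numeric(0), y_um = numeric(0),
                       degree = integer(0), class = character(0)),
    segments = data.frame(from = integer(0), to = integer(0),
                          length_um = numeric(0), class = character(0)),
    meshes = data.frame(area_um2 = numeric(0)),
    skeleton = mask & FALSE, n_components = 0L)
  class(empty) <- "TubeNetwork"
  if (!any(mask)) return(empty)

  sk <- thin_mask(mask)
  if (!any(sk)) return(empty)
  gr <- trace_skeleton(sk)
  sg <- simplify_skeleton_graph(gr, prune_px = um_to_px(prune_len, pixel_size),
                                fuse_px = max(1.5, um_to_px(fuse_len, pixel_size)))
  edges <- sg$edges
  ids <- sort(unique(c(edges$from, edges$to)))
  deg <- vapply(ids, function(v)
    sum(edges$from == v) + sum(edges$to == v), numeric(1))
  cls <- ifelse(deg >= 3, "junction",
                ifelse(deg == 1, "extremity", "path"))
  id_class <- stats::setNames(cls, ids)
  seg_class <- vapply(seq_len(nrow(edges)), function(i) {
    if (identical(id_class[[as.character(edges$from[i])]], "junction") &&
        identical(id_class[[as.character(edges$to[i])]], "junction"))
      "master" else "branch"
  }, character(1))
  master_j <- unique(c(edges$from[seg_class == "master"],
                       edges$to[seg_class == "master"]))
  cls[ids %in% master_j & cls == "junction"] <- "master_junction"

  nodes <- data.frame(
    x_um = (sg$centres[ids, 2] - 1) * pixel_size,
    y_um = (sg$centres[ids, 1] - 1) * pixel_size,
    degree = as.integer(deg), class = cls)
  rownames(nodes) <- NULL
  segments <- data.frame(from = match(edges$from, ids),
                         to = match(edges$to, ids),
                         length_um = edges$len * pixel_size,
                         class = seg_class)

  # meshes: enclosed faces of the skeleton
  bg <- !sk
  lb <- as.matrix(EBImage::bwlabel(EBImage::Image(bg)))
  border_labs <- unique(c(lb[1, ], lb[nrow(lb), ], lb[, 1], lb[, ncol(lb)]))
  face_labs <- setdiff(sort(unique(as.vector(lb))), c(0L, border_labs))
  mesh_areas <- if (length(face_labs))
    tabulate(lb[lb > 0])[face_labs] * pixel_size^2 else numeric(0)

  comps <- n_graph_components(edges, ids)
  structure(list(nodes = nodes, segments = segments,
                 meshes = data.frame(area_um2 = mesh_areas),
                 skeleton = sk, n_components = comps),
            class = "TubeNetwork")
}

n_graph_components <- function(edges, ids) {
  if (!length(ids)) return(0L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  igraph::count_components(g)
}

#' The six angiogenesis parameters of a tube network
#'
#' @param net a `TubeNetwork` from [skeleton_graph()].
#' @return an `AngioParams` named numeric vector: `n_junctions`,
#'   `n_master_junctions`, `n_master_segments`, `total_master_length`
#'   (um), `n_meshes`, `total_mesh_area` (um^2).
#' @export
angio_params <- function(net) {
  jn <- net$nodes$class %in% c("junction", "master_junction")
  ms <- net$segments$class == "master"
  structure(c(
    n_junctions = sum(jn),
    n_master_junctions = sum(net$nodes$class == "master_junction"),
    n_master_segments = sum(ms),
    total_master_length = sum(net$segments$length_um[ms]),
    n_meshes = nrow(net$meshes),
    total_mesh_area = sum(net$meshes$area_um2)),
    class = "AngioParams")
}

#' Control-normalised angiogenesis index
#'
#' Mean of the six per-parameter ratios treated/control; 1.0 means
#' control-level tube formation. Every control parameter must be
#' positive, otherwise its ratio is undefined and an error names the
#' offending parameter.
#'
#' @param treated,control `AngioParams` (or named numeric vectors with
#'   the six parameters).
#' @return an `AngioIndex` list: `value` and `ratios`.
#' @export
angiogenesis_index <- function(treated, control) {
  nm <- c("n_junctions", "n_master_junctions", "n_master_segments",
          "total_master_length", "n_meshes", "total_mesh_area")
  t_ <- unclass(treated)[nm]; c_ <- unclass(control)[nm]
  if (anyNA(t_) || anyNA(c_))
    stop_cm("validation_error", "treated/control must carry all six parameters")
  bad <- nm[c_ <= 0]
  if (length(bad))
    stop_cm("undefined_ratio_error",
            "control parameter not positive: ", paste(bad, collapse = ", "))
  ratios <- t_ / c_
  structure(list(value = mean(ratios), ratios = ratios),
            class = "AngioIndex")
}

#' @export
print.AngioIndex <- function(x, ...) {
  cat(sprintf("Angiogenesis index: %.3f (1.0 = control)\n", x$value))
  print(round(x$ratios, 3))
  invisible(x)
}
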