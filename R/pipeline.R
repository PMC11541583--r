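#' Batch pipeline runner
#'
#' One entry point drives every analysis in the package from a plain
#' configuration (an R list, or a YAML file via [load_config()]):
#' `pipeline` selects `"stellate"`, `"organoid"`, `"tubes"`, `"track"`,
#' `"phantom"` or `"scores"`; the remaining fields name inputs,
#' parameters and the output directory. Each run writes one or more
#' metrics CSVs plus a plain-text log of every parameter actually used
#' (including defaults) and the random seed. All randomness flows from
#' the single integer `seed` (default 0), so identical configurations
#' produce byte-identical outputs.
#'
#' @param config a named list, or a path to a YAML config file.
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- load_config(config)
  if (!is.list(config) || is.null(config$pipeline))
    stop_cm("usage_error", "config must name a pipeline")
  known <- c("stellate", "organoid", "tubes", "track", "phantom", "scores")
  if (!config$pipeline %in% known)
    stop_cm("usage_error", "unknown pipeline '", config$pipeline,
            "'; expected one of: ", paste(known, collapse = ", "))
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(config$seed %||% 0L)
  set.seed(config$seed)
  res <- switch(config$pipeline,
    stellate = pipeline_stellate(config, out_dir),
    organoid = pipeline_organoid(config, out_dir),
    tubes = pipeline_tubes(config, out_dir),
    track = pipeline_track(config, out_dir),
    phantom = pipeline_phantom(config, out_dir),
    scores = pipeline_scores(config, out_dir))
  write_run_log(config, res$effective, out_dir)
  invisible(res$outputs)
}

#' Load a YAML run configuration
#'
#' @param path YAML file.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_cm("usage_error", "config not found: ", path)
  yaml::read_yaml(path)
}

write_run_log <- function(config, effective, out_dir) {
  path <- file.path(out_dir, paste0(config$pipeline, "_run.log"))
  lines <- c(
    paste0("pipeline: ", config$pipeline),
    paste0("cytomorph_version: ",
           as.character(utils::packageVersion("cytomorph"))),
    paste0("seed: ", config$seed),
    "effective_parameters:",
    vapply(names(effective), function(n)
      paste0("  ", n, ": ", paste(format(effective[[n]]), collapse = " ")),
      character(1)))
  writeLines(lines, path)
  path
}

list_tiffs <- function(dir) {
  if (is.null(dir) || !dir.exists(dir))
    stop_cm("usage_error", "input directory not found: ", dir %||% "<missing>")
  fs <- sort(list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE))
  if (!length(fs)) stop_cm("usage_error", "no TIFF files in ", dir)
  fs
}

pipeline_stellate <- function(cfg, out_dir) {
  eff <- list(input = cfg$input, pixel_size = cfg$pixel_size %||% 1,
              ball_radius = cfg$ball_radius %||% 250,
              sigma = cfg$sigma %||% 15,
              d_hi = cfg$d_hi %||% 0.75, d_lo = cfg$d_lo %||% 0.35,
              invert = cfg$invert %||% TRUE,
              channel = cfg$channel %||% "brightfield",
              exclude_dir = cfg$exclude_dir %||% "<none>")
  rows <- list()
  for (f in list_tiffs(cfg$input)) {
    fr <- read_image(f, eff$pixel_size, channel = eff$channel)
    excl <- NULL
    if (!identical(eff$exclude_dir, "<none>")) {
      ef <- file.path(eff$exclude_dir, basename(f))
      if (file.exists(ef))
        excl <- read_image(ef, eff$pixel_size)$pixels > 0
    }
    an <- analyze_stellate(fr, ball_radius = eff$ball_radius,
                           sigma = eff$sigma, d_hi = eff$d_hi,
                           d_lo = eff$d_lo, invert = eff$invert,
                           exclude = excl)
    m <- an$metrics
    rows[[length(rows) + 1]] <- data.frame(
      image_id = tools::file_path_sans_ext(basename(f)),
      inner_circularity = m$inner_circularity,
      inner_area_um2 = m$inner_area, outer_area_um2 = m$outer_area,
      peripheral_area_um2 = m$peripheral_area)
  }
  out <- file.path(out_dir, "stellate.csv")
  write_metrics(do.call(rbind, rows), out)
  list(outputs = list(stellate = out), effective = eff)
}

pipeline_organoid <- function(cfg, out_dir) {
  eff <- list(live = cfg$live, dead = cfg$dead,
              pixel_size = cfg$pixel_size %||% 1,
              cell_diameter = cfg$cell_diameter %||% 8,
              live_thresh = cfg$live_thresh %||% 0.6,
              dead_thresh = cfg$dead_thresh %||% 0.5,
              spheroid_thresh = cfg$spheroid_thresh %||% 0.15,
              min_area = cfg$min_area %||% "<default>")
  lf <- list_tiffs(cfg$live); df <- list_tiffs(cfg$dead)
  if (length(lf) != length(df))
    stop_cm("usage_error", "live/dead directories must pair one-to-one")
  rec <- list(); summ <- list()
  for (i in seq_along(lf)) {
    id <- tools::file_path_sans_ext(basename(lf[i]))
    live_fr <- read_image(lf[i], eff$pixel_size, channel = "calcein")
    dead_fr <- read_image(df[i], eff$pixel_size, channel = "ethidium")
    live <- detect_live_cells(live_fr, eff$cell_diameter, eff$live_thresh)
    dead <- detect_dead_cells(dead_fr, eff$cell_diameter, eff$dead_thresh)
    min_area <- if (identical(eff$min_area, "<default>")) NULL else eff$min_area
    sph <- detect_spheroids(live_fr, eff$spheroid_thresh,
                            min_area = min_area,
                            cell_diameter = eff$cell_diameter)
    st <- spheroid_stats(sph, live, dead, live_fr, dead_fr, eff$pixel_size)
    if (nrow(st$records))
      rec[[length(rec) + 1]] <- cbind(image_id = id, st$records)
    summ[[length(summ) + 1]] <-
      data.frame(image_id = id, spheroid_count = st$summary$spheroid_count)
  }
  out1 <- file.path(out_dir, "organoid.csv")
  out2 <- file.path(out_dir, "organoid_summary.csv")
  empty_rec <- data.frame(image_id = character(0), spheroid_id = integer(0),
                          area_um2 = numeric(0), circularity = numeric(0),
                          live_count = integer(0), dead_count = integer(0),
                          live_mean_int = numeric(0),
                          dead_mean_int = numeric(0))
  write_metrics(if (length(rec)) do.call(rbind, rec) else empty_rec, out1)
  write_metrics(do.call(rbind, summ), out2)
  list(outputs = list(organoid = out1, organoid_summary = out2),
       effective = eff)
}

pipeline_tubes <- function(cfg, out_dir) {
  eff <- list(input = cfg$input, pixel_size = cfg$pixel_size %||% 1,
              ball_radius = cfg$ball_radius %||% 50,
              prune_len = cfg$prune_len %||% 10,
              min_object_area = cfg$min_object_area %||% 100,
              control_label = cfg$control_label %||% "<none>")
  groups <- cfg$groups %||% list()
  rows <- list(); params_by_group <- list()
  for (f in list_tiffs(cfg$input)) {
    id <- tools::file_path_sans_ext(basename(f))
    fr <- read_image(f, eff$pixel_size, channel = "tubes")
    mask <- binarize_network(fr, eff$ball_radius,
                             min_object_area = eff$min_object_area)
    net <- skeleton_graph(mask, eff$pixel_size, eff$prune_len)
    ap <- angio_params(net)
    rows[[length(rows) + 1]] <- data.frame(
      image_id = id, junctions = ap[["n_junctions"]],
      master_junctions = ap[["n_master_junctions"]],
      master_segments = ap[["n_master_segments"]],
      master_len_um = ap[["total_master_length"]],
      meshes = ap[["n_meshes"]], mesh_area_um2 = ap[["total_mesh_area"]])
    g <- groups[[id]] %||% "<ungrouped>"
    params_by_group[[g]] <- c(params_by_group[[g]], list(unclass(ap)))
  }
  out1 <- file.path(out_dir, "tubes.csv")
  write_metrics(do.call(rbind, rows), out1)
  outputs <- list(tubes = out1)
  if (!identical(eff$control_label, "<none>") &&
      eff$control_label %in% names(params_by_group)) {
    gm <- lapply(params_by_group, function(ps) Reduce(`+`, ps) / length(ps))
    ctrl <- gm[[eff$control_label]]
    idx_rows <- lapply(names(gm), function(g) {
      ai <- angiogenesis_index(structure(gm[[g]], class = "AngioParams"),
                               structure(ctrl, class = "AngioParams"))
      data.frame(group = g, angio_index = ai$value)
    })
    out2 <- file.path(out_dir, "angio_index.csv")
    write_metrics(do.call(rbind, idx_rows), out2)
    outputs$angio_index <- out2
  }
  list(outputs = outputs, effective = eff)
}

pipeline_track <- function(cfg, out_dir) {
  eff <- list(input = cfg$input, pixel_size = cfg$pixel_size %||% 1,
              frame_interval = cfg$frame_interval %||% 20,
              diameter = cfg$diameter %||% 18,
              intensity_lo = cfg$intensity_lo %||% 30,
              intensity_hi = cfg$intensity_hi %||% 230,
              max_dist = cfg$max_dist %||% 20,
              max_gap = cfg$max_gap %||% 5)
  if (is.null(cfg$input) || !file.exists(cfg$input))
    stop_cm("usage_error", "input movie not found: ", cfg$input %||% "<missing>")
  stack <- read_image(cfg$input, eff$pixel_size, channel = "mKO2",
                      axis = "t", spacing = eff$frame_interval * 60)
  if (is_image_frame(stack))
    stack <- image_stack(list(stack), axis = "t",
                         spacing = eff$frame_interval * 60)
  spots <- detect_spots_stack(stack, eff$diameter,
                              c(eff$intensity_lo, eff$intensity_hi))
  tracks <- link_tracks(spots, eff$max_dist, eff$max_gap)
  summ <- summarize_tracks(tracks, eff$frame_interval)
  out1 <- file.path(out_dir, "tracks.csv")
  out2 <- file.path(out_dir, "track_summary.csv")
  write_metrics(tracks, out1)
  write_metrics(summ[, c("track_id", "mean_speed_um_per_min")], out2)
  list(outputs = list(tracks = out1, track_summary = out2), effective = eff)
}

pipeline_phantom <- function(cfg, out_dir) {
  kind <- cfg$kind %||%
    stop_cm("usage_error", "phantom pipeline needs a 'kind'")
  args <- cfg[setdiff(names(cfg), c("pipeline", "kind", "out"))]
  outputs <- list()
  if (kind == "stellate") {
    ph <- do.call(make_stellate, args)
    outputs$image <- file.path(out_dir, "phantom_stellate.tif")
    write_image(ph$image, outputs$image)
  } else if (kind == "organoid") {
    ph <- do.call(make_organoid_field, args)
    outputs$green <- file.path(out_dir, "phantom_organoid_green.tif")
    outputs$orange <- file.path(out_dir, "phantom_organoid_orange.tif")
    write_image(ph$green, outputs$green)
    write_image(ph$orange, outputs$orange)
  } else if (kind == "tubes") {
    ph <- do.call(make_tube_lattice, args)
    outputs$image <- file.path(out_dir, "phantom_tubes.tif")
    write_image(ph$image, outputs$image)
  } else if (kind == "tracks") {
    ph <- do.call(make_track_movie, args)
    outputs$movie <- file.path(out_dir, "phantom_tracks.tif")
    write_image(ph$movie, outputs$movie)
  } else {
    stop_cm("usage_error", "unknown phantom kind '", kind, "'")
  }
  outputs$truth <- file.path(out_dir, paste0("phantom_", kind, "_truth.json"))
  write_phantom_truth(ph$truth, outputs$truth)
  eff <- c(list(kind = kind), args)
  list(outputs = outputs, effective = eff)
}

pipeline_scores <- function(cfg, out_dir) {
  mode <- cfg$mode %||% stop_cm("usage_error",
                                "scores pipeline needs mode 'volume' or 'ihc'")
  if (is.null(cfg$input) || !file.exists(cfg$input))
    stop_cm("usage_error", "input CSV not found: ", cfg$input %||% "<missing>")
  tab <- read_metrics(cfg$input)
  if (mode == "volume") {
    if (!all(c("d1_mm", "d2_mm") %in% names(tab)))
      stop_cm("usage_error", "calipers CSV needs columns d1_mm, d2_mm")
    tab$volume_mm3 <- tumour_volume(tab$d1_mm, tab$d2_mm)
    out <- file.path(out_dir, "volumes.csv")
  } else if (mode == "ihc") {
    if (!all(c("percent_positive", "intensity_grade") %in% names(tab)))
      stop_cm("usage_error",
              "grades CSV needs columns percent_positive, intensity_grade")
    sc <- ihc_score(tab$percent_positive, tab$intensity_grade)
    tab$positivity_bin <- sc$positivity_bin
    tab$total_score <- sc$total
    out <- file.path(out_dir, "ihc_scores.csv")
  } else stop_cm("usage_error", "unknown scores mode '", mode, "'")
  write_metrics(tab, out)
  list(outputs = list(scores = out),
       effective = list(mode = mode, input = cfg$input))
}
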