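# Per-frame and per-series orchestration: compose topology, morphometrics,
# geometry and the Voronoi null into figure-level summary tables.

#' Analyse a single labelled frame
#'
#' Runs layer extraction, band selection, scutoid detection, per-cell
#' morphometrics, tissue geometry and (optionally) the matched Voronoi null
#' comparison, returning the per-frame summary row plus the per-cell table.
#' A failing stage is recorded and leaves its fields `NA` instead of
#' aborting, so long time-lapses survive one bad frame.
#'
#' @param volume a [label_volume()].
#' @param config a [run_config()].
#' @param features character vector choosing the per-cell and tissue
#'   features to compute; any of `"convexity"`, `"height"`, `"sra"`,
#'   `"surface_ratio"`, `"openings"`, or `"all"` (default).
#' @param null_model logical: build and measure the Voronoi null
#'   construction (default `TRUE`).
#' @return List of class `frame_summary`: `summary` (one-row data frame),
#'   `cells` (per-cell data frame), `calls`, `layers`, and `errors`
#'   (named character vector of stage failures, if any).
#' @export
run_frame <- function(volume, config = run_config(), features = "all",
                      null_model = TRUE) {
  if ("all" %in% features)
    features <- c("convexity", "height", "sra", "surface_ratio", "openings")
  errors <- character(0)
  note <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      NULL
    })
  }
  note_na <- function(stage, expr) {
    out <- note(stage, expr)
    if (is.null(out)) NA_real_ else out
  }

  layers <- extract_layers(volume)
  selected <- select_band(volume, config$band_depth, layers)
  calls <- detect_scutoids(layers, config, selected)
  prop <- scutoid_proportion(calls)

  vols <- cell_volumes(volume)
  cen <- cell_centroids(volume)
  bas <- note("basal_areas", basal_areas(layers))
  cells <- merge(cen, vols, by = "cell_id", all = TRUE)
  if (!is.null(bas)) cells <- merge(cells, bas, by = "cell_id", all.x = TRUE)
  else cells$basal_area <- NA_real_

  counted_ids <- calls$cell_id[calls$counted]
  cells$convexity <- NA_real_
  if ("convexity" %in% features) {
    for (id in counted_ids)
      cells$convexity[cells$cell_id == id] <-
        note_na(paste0("convexity_", id), cell_convexity(volume, id))
  }
  cells$height <- NA_real_
  if ("height" %in% features) {
    for (id in counted_ids)
      cells$height[cells$cell_id == id] <-
        note_na(paste0("height_", id), cell_height(volume, layers, id))
  }
  cells <- merge(cells, as.data.frame(calls), by = "cell_id", all.x = TRUE)
  if (!is.null(volume$frame_index)) cells$frame <- volume$frame_index

  density <- note("density", cell_density(calls, cells))
  sra_rec <- if ("sra" %in% features)
    note("sra", surface_ratio_anisotropy(volume, layers, selected,
                                         config$sr_ratio_order)) else NULL
  sr <- if ("surface_ratio" %in% features)
    note("surface_ratio", tissue_surface_ratio(layers)) else NULL
  op <- if ("openings" %in% features)
    note("openings", opening_areas(volume, config$min_opening_area)) else NULL
  nc <- if (null_model) note("voronoi_null", null_comparison(volume, config)) else NULL

  sel_cells <- cells[cells$cell_id %in% counted_ids, , drop = FALSE]
  stage <- volume$stage_label
  if (is.null(stage)) stage <- stage_from_count(nrow(cen))
  summary <- data.frame(
    frame = if (!is.null(volume$frame_index)) volume$frame_index else NA_integer_,
    stage = stage,
    n_cells = nrow(cen),
    n_selected = length(selected),
    n_counted = sum(calls$counted),
    scutoid_proportion = prop,
    density = if (is.null(density)) NA_real_ else density,
    mean_volume = mean(sel_cells$volume, na.rm = TRUE),
    mean_convexity = if ("convexity" %in% features)
      mean(sel_cells$convexity, na.rm = TRUE) else NA_real_,
    mean_height = if ("height" %in% features)
      mean(sel_cells$height, na.rm = TRUE) else NA_real_,
    sra = if (is.null(sra_rec)) NA_real_ else sra_rec$sra,
    surface_ratio = if (is.null(sr)) NA_real_ else sr,
    opening_area_sum = if (is.null(op)) NA_real_ else attr(op, "sum"),
    voronoi_proportion = if (is.null(nc)) NA_real_ else nc$voronoi_proportion,
    excess = if (is.null(nc)) NA_real_ else nc$excess,
    stringsAsFactors = FALSE)
  structure(list(summary = summary, cells = cells, calls = calls,
                 layers = layers, anisotropy = sra_rec, null = nc,
                 errors = errors),
            class = "frame_summary")
}

stage_from_count <- function(n) {
  if (n < 1) return(NA_character_)
  paste0(2^round(log2(n)), "-cell")
}

#' Analyse a simulated or stored time-lapse series
#'
#' Runs [run_frame()] over every frame, then the dynamics stage (scutoid
#' tracking over interphases, onset normalization and classification) when
#' interphase bounds are available, and aggregates per-stage means and
#' standard deviations.
#'
#' @param x a [timelapse_spec()] (frames are simulated), a list of
#'   [label_volume()]s, or a directory containing multi-page TIFF frames
#'   (read in sorted order; spacing must agree across frames).
#' @param config a [run_config()].
#' @param features,null_model passed to [run_frame()].
#' @param events optional event table (`cell_id, interphase_start,
#'   interphase_end`) for stored series; simulated series carry their own.
#' @return List of class `series_summary`: `summaries` (per-frame data
#'   frame), `events` (normalized, classified scutoid events or `NULL`),
#'   `stage_stats`, and `frames` (the per-frame results).
#' @export
run_series <- function(x, config = run_config(), features = "all",
                       null_model = TRUE, events = NULL) {
  if (inherits(x, "timelapse_spec")) {
    sim <- simulate_division_series(x)
    volumes <- sim$volumes
    if (is.null(events)) events <- sim$events
  } else if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) stop("no such directory: ", x)
    paths <- sort(list.files(x, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(paths)) stop("no TIFF frames found in ", x)
    volumes <- lapply(paths, read_label_volume)
    for (f in seq_along(volumes)) {
      if (is.null(volumes[[f]]$frame_index)) volumes[[f]]$frame_index <- f
    }
  } else if (is.list(x)) {
    volumes <- x
  } else stop("unsupported input to run_series()")

  spacings <- vapply(volumes, function(v) v$spacing, numeric(3))
  if (any(apply(spacings, 1, function(r) diff(range(r)) > 1e-9)))
    stop("inconsistent voxel spacing across frames")

  frames <- lapply(volumes, run_frame, config = config, features = features,
                   null_model = null_model)
  summaries <- do.call(rbind, lapply(frames, function(f) f$summary))
  summaries$frame[is.na(summaries$frame)] <- seq_len(nrow(summaries))[is.na(summaries$frame)]

  ev_out <- NULL
  if (!is.null(events)) {
    tracked <- track_scutoid_events(lapply(frames, function(f) f$calls), events)
    if (nrow(tracked)) {
      tracked <- normalize_events(tracked)
      tracked$onset_class <- classify_onset(tracked$onset_norm,
                                            config$onset_threshold)
    }
    ev_out <- tracked
  }

  num <- c("scutoid_proportion", "density", "mean_volume", "mean_convexity",
           "mean_height", "sra", "surface_ratio", "opening_area_sum",
           "voronoi_proportion", "excess")
  stage_stats <- do.call(rbind, lapply(split(summaries, summaries$stage), function(g) {
    out <- data.frame(stage = g$stage[1], n_frames = nrow(g))
    for (cn in num) {
      out[[paste0(cn, "_mean")]] <- mean(g[[cn]], na.rm = TRUE)
      out[[paste0(cn, "_sd")]] <- stats::sd(g[[cn]])
    }
    out
  }))
  rownames(stage_stats) <- NULL
  structure(list(summaries = summaries, events = ev_out,
                 stage_stats = stage_stats, frames = frames),
            class = "series_summary")
}

#' Write the per-frame summary and event tables of a series
#'
#' @param series a [run_series()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series_tables <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(series$summaries, file.path(dir, "frame_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(series$stage_stats, file.path(dir, "stage_stats.csv"),
                   row.names = FALSE)
  if (!is.null(series$events))
    utils::write.csv(series$events, file.path(dir, "scutoid_events.csv"),
                     row.names = FALSE)
  for (f in seq_along(series$frames))
    write_cell_table(series$frames[[f]]$cells,
                     file.path(dir, sprintf("cells_frame%03d.csv", f)))
  invisible(dir)
}
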