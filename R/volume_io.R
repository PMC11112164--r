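#' Labelled 3D segmentation volume
#'
#' The central container of the package: a 3D integer array in array order
#' `(z, y, x)` holding one positive integer label per segmented cell and 0 for
#' background, together with the physical voxel spacing in micrometres.
#'
#' Coordinate conventions, shared by every function in the package:
#' * arrays are indexed `[z, y, x]`; z index 1 is the slice closest to the
#'   objective, so the top-down z-scan meets the apical surface first;
#' * grid-attached triples (`spacing`, array `dim`) are in the same
#'   `(z, y, x)` order; `spacing = c(dz, dy, dx)` in micrometres;
#' * free point coordinates (centroids, seeds, fitted centres) are matrices
#'   or data frames with columns `x, y, z` in micrometres, where the physical
#'   centre of voxel `[k, i, j]` is `((j - 0.5) dx, (i - 0.5) dy, (k - 0.5) dz)`.
#'
#' @param voxels 3D integer array `(z, y, x)`; values `>= 0`, 0 = background.
#' @param spacing numeric length-3, `c(dz, dy, dx)` in micrometres, all `> 0`.
#' @param frame_index optional integer time-lapse frame number (1-based).
#' @param stage_label optional text such as `"256-cell"`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing, frame_index = NULL, stage_label = NULL) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, y, x)")
  if (any(voxels < 0, na.rm = TRUE))
    stop("labels must be >= 0 (0 = background)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (dz, dy, dx) in um")
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         frame_index = frame_index, stage_label = stage_label),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- volume_labels(x)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  %d cells%s%s\n", length(labs),
              if (!is.null(x$frame_index)) sprintf(", frame %d", x$frame_index) else "",
              if (!is.null(x$stage_label)) sprintf(", stage %s", x$stage_label) else ""))
  invisible(x)
}

#' Labels present in a volume
#'
#' @param volume a [label_volume()].
#' @return Sorted integer vector of positive labels present.
#' @export
volume_labels <- function(volume) {
  u <- sort(unique(as.integer(volume$voxels)))
  u[u > 0L]
}

#' Physical voxel-centre coordinate axes of a volume
#'
#' @param volume a [label_volume()] (or anything with `$voxels` and `$spacing`).
#' @return List with numeric vectors `z`, `y`, `x` of voxel-centre positions (um).
#' @keywords internal
voxel_axes <- function(volume) {
  d <- dim(volume$voxels); sp <- volume$spacing
  list(z = (seq_len(d[1]) - 0.5) * sp[1],
       y = (seq_len(d[2]) - 0.5) * sp[2],
       x = (seq_len(d[3]) - 0.5) * sp[3])
}

#' Per-cell 3D centroids in physical coordinates
#'
#' @param volume a [label_volume()].
#' @param labels labels to compute; defaults to all present.
#' @return Data frame with columns `cell_id`, `x`, `y`, `z` (um).
#' @export
cell_centroids <- function(volume, labels = volume_labels(volume)) {
  v <- volume$voxels
  ax <- voxel_axes(volume)
  idx <- which(v != 0L & v %in% labels)
  lab <- v[idx]
  d <- dim(v)
  k <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  i <- rest %% d[2] + 1L
  j <- rest %/% d[2] + 1L
  f <- factor(lab, levels = sort(unique(lab)))
  out <- data.frame(
    cell_id = as.integer(levels(f)),
    x = as.numeric(tapply(ax$x[j], f, mean)),
    y = as.numeric(tapply(ax$y[i], f, mean)),
    z = as.numeric(tapply(ax$z[k], f, mean)))
  rownames(out) <- NULL
  out[match(labels[labels %in% out$cell_id], out$cell_id), , drop = FALSE]
}

#' Analysis run configuration
#'
#' Bundles the tunable parameters shared across the pipeline.
#'
#' @param band_depth selection band in micrometres: cells whose centroid lies
#'   within this z-distance of the apical surface (the embryo surface closest
#'   to the objective) are selected for analysis. Default 30.
#' @param onset_threshold fraction of interphase below which a scutoid onset
#'   is classed as occurring after mitosis (strict `<`). Default 0.15.
#' @param dilation_radius structuring-element radius in pixels for the
#'   neighbour-set dilation on layer maps. Default 1 (8-connectivity).
#' @param min_opening_area smallest background component (um^2) reported as an
#'   epithelial opening. Default 5.
#' @param border_policy `"exclude"` (default) drops cells whose apical or
#'   basal footprint touches the image boundary from both numerator and
#'   denominator of the scutoid proportion; `"include-flagged"` keeps them
#'   but leaves the border flag set.
#' @param rng_seed integer seed for any stochastic step.
#' @param reuse_band logical; if `TRUE`, the Voronoi null construction reuses
#'   the observed frame's band selection instead of recomputing its own.
#' @param sr_ratio_order `"average_then_ratio"` (default) averages radii of
#'   curvature per surface before taking apical/basal ratios;
#'   `"ratio_then_average"` averages per-cell ratios instead.
#' @return An object of class `run_config`.
#' @export
run_config <- function(band_depth = 30, onset_threshold = 0.15,
                       dilation_radius = 1L, min_opening_area = 5,
                       border_policy = c("exclude", "include-flagged"),
                       rng_seed = 1L, reuse_band = FALSE,
                       sr_ratio_order = c("average_then_ratio", "ratio_then_average")) {
  border_policy <- match.arg(border_policy)
  sr_ratio_order <- match.arg(sr_ratio_order)
  if (!is.finite(band_depth) || band_depth <= 0) stop("band_depth must be > 0")
  if (!is.finite(onset_threshold) || onset_threshold <= 0 || onset_threshold >= 1)
    stop("onset_threshold must be in (0, 1)")
  if (dilation_radius < 1) stop("dilation_radius must be >= 1")
  structure(list(band_depth = band_depth, onset_threshold = onset_threshold,
                 dilation_radius = as.integer(dilation_radius),
                 min_opening_area = min_opening_area,
                 border_policy = border_policy, rng_seed = as.integer(rng_seed),
                 reuse_band = isTRUE(reuse_band), sr_ratio_order = sr_ratio_order),
            class = "run_config")
}

#' Read/write run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read a labelled volume from a multi-page TIFF
#'
#' One TIFF page per z slice; integer pixel values are cell labels. Voxel
#' spacing is taken from a sidecar JSON (`<path>.json`, written by
#' [write_label_volume()]) unless overridden.
#'
#' @param path TIFF file path.
#' @param spacing optional `c(dz, dy, dx)` um override; required when no
#'   sidecar metadata is present.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages do not share dimensions")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  # readTIFF normalizes to [0, 1]; integer-sample TIFFs land exactly on the
  # k / (2^bits - 1) grid, float-sample TIFFs do not
  scale <- 2^bits - 1
  pages <- lapply(pages, function(p) p * scale)
  vals <- unlist(pages, use.names = FALSE)
  if (any(abs(vals - round(vals)) > 0.01) || any(vals < -0.5))
    stop("non-integer pixel data: a label volume must hold integer labels")
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(spacing)) {
    if (is.null(meta$spacing))
      stop("no spacing metadata found for ", path, "; pass `spacing`")
    spacing <- as.numeric(meta$spacing)
  }
  nz <- length(pages); ny <- dims[1, 1]; nx <- dims[2, 1]
  if (nz == 1L)
    warning("single-page TIFF: n_z = 1, no apical/basal distinction possible")
  vox <- array(0L, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) vox[k, , ] <- as.integer(round(pages[[k]]))
  label_volume(vox, spacing,
               frame_index = if (!is.null(meta$frame_index)) meta$frame_index,
               stage_label = if (!is.null(meta$stage_label)) meta$stage_label)
}

#' Write a labelled volume to a multi-page TIFF plus JSON sidecar
#'
#' Labels are stored as 16-bit unsigned pages (max label 65535); spacing and
#' frame metadata go to `<path>.json`.
#'
#' @param volume a [label_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  v <- volume$voxels
  if (max(v) > 65535L) stop("labels exceed 16-bit range")
  nz <- dim(v)[1]
  pages <- lapply(seq_len(nz), function(k) v[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(spacing = volume$spacing, frame_index = volume$frame_index,
         stage_label = volume$stage_label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a per-cell feature table to CSV
#'
#' One row per cell with a documented, stable column order. All records must
#' come from the same frame; duplicate cell ids are an error.
#'
#' @param records data frame of per-cell records (must contain `cell_id`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  lead <- c("cell_id", "frame", "x", "y", "z", "volume", "convexity", "height",
            "basal_area", "apical_neighbours", "basal_neighbours",
            "is_scutoid", "is_border", "is_selected")
  if (nrow(records) > 0) {
    if (!"cell_id" %in% names(records)) stop("records must contain `cell_id`")
    if (anyDuplicated(records$cell_id)) stop("duplicate cell ids in records")
    if ("frame" %in% names(records) && length(unique(records$frame)) > 1)
      stop("records must share a single frame index")
  }
  ord <- c(intersect(lead, names(records)), setdiff(names(records), lead))
  utils::write.csv(records[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell feature table written by [write_cell_table()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
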