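# 3D Voronoi constructions: proximity tiling of a binary mask from seed
# points, used both as the static geometric null model matched to an observed
# frame and as the generative engine of the synthetic epithelium phantoms.

#' Tile a binary mask by proximity to seed points
#'
#' Every in-mask voxel receives the label of its nearest seed, with distance
#' measured between physical voxel centres and seed coordinates (anisotropic
#' spacing honoured). Voxels equidistant to several seeds go to the lowest
#' label id, so the construction is fully deterministic.
#'
#' @param centroids numeric matrix or data frame of seed coordinates, columns
#'   `x, y, z` in um. Labels are taken from a `cell_id`/`label` column or
#'   rownames when present, else `1..n`.
#' @param mask 3D logical array `(z, y, x)`: the territory to tile.
#' @param spacing `c(dz, dy, dx)` voxel spacing in um.
#' @return A `label_volume` subclassed as `voronoi_construction`, carrying the
#'   seed table as attribute `"seeds"`.
#' @export
voronoi_construct <- function(centroids, mask, spacing) {
  seeds <- as_seed_table(centroids)
  if (nrow(seeds) == 0L) stop("no seeds given")
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  mask <- mask != 0
  d <- dim(mask)
  ax <- voxel_axes(list(voxels = mask, spacing = spacing))
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  k <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  i <- rest %% d[2] + 1L
  j <- rest %/% d[2] + 1L
  vx <- ax$x[j]; vy <- ax$y[i]; vz <- ax$z[k]

  # seeds outside the mask are kept (no projection step), but flagged
  si <- pmin(pmax(round(seeds$y / spacing[2] + 0.5), 1L), d[2])
  sj <- pmin(pmax(round(seeds$x / spacing[3] + 0.5), 1L), d[3])
  sk <- pmin(pmax(round(seeds$z / spacing[1] + 0.5), 1L), d[1])
  inmask <- mask[cbind(sk, si, sj)]
  if (any(!inmask))
    warning(sum(!inmask), " seed(s) fall outside the mask; kept as given")

  ord <- order(seeds$cell_id)  # ascending labels => ties resolve to lowest id
  best <- rep(Inf, length(idx))
  lab <- integer(length(idx))
  for (s in ord) {
    d2 <- (vx - seeds$x[s])^2 + (vy - seeds$y[s])^2 + (vz - seeds$z[s])^2
    upd <- d2 < best
    if (any(upd)) {
      best[upd] <- d2[upd]
      lab[upd] <- seeds$cell_id[s]
    }
  }
  vox <- array(0L, dim = d)
  vox[idx] <- lab
  out <- label_volume(vox, spacing)
  class(out) <- c("voronoi_construction", class(out))
  attr(out, "seeds") <- seeds
  out
}

as_seed_table <- function(centroids) {
  m <- as.data.frame(centroids)
  if (!all(c("x", "y", "z") %in% names(m))) {
    if (ncol(m) >= 3) names(m)[1:3] <- c("x", "y", "z")
    else stop("centroids need columns x, y, z")
  }
  id_col <- intersect(c("cell_id", "label"), names(m))
  ids <- if (length(id_col)) as.integer(m[[id_col[1]]])
         else if (!is.null(rownames(centroids)) &&
                  !anyNA(suppressWarnings(as.integer(rownames(centroids)))) &&
                  !all(rownames(centroids) == seq_len(nrow(m))))
           as.integer(rownames(centroids))
         else seq_len(nrow(m))
  if (anyDuplicated(ids)) stop("duplicate seed labels")
  data.frame(cell_id = ids, x = m$x, y = m$y, z = m$z)
}

#' Compare an observed frame with its matched Voronoi null construction
#'
#' Builds the steady-state null model of a segmented frame (same binary mask,
#' seeds at the frame's cell centroids), then measures the scutoid proportion
#' of observation and construction with the identical layer-extraction,
#' band-selection and scutoid-detection code path, so any excess is
#' attributable to geometry alone.
#'
#' When `observed` is itself a `voronoi_construction`, its recorded seed set
#' (by construction, the centroid set of its source frame) is reused, making
#' the comparison idempotent: the rebuilt construction is bit-identical and
#' the excess is exactly 0.
#'
#' @param observed a [label_volume()].
#' @param config a [run_config()]; `reuse_band = TRUE` reuses the observed
#'   band selection for the construction instead of recomputing it.
#' @param seeds optional explicit seed table overriding the default
#'   (centroids of `observed`).
#' @return List of class `null_comparison`: `observed_proportion`,
#'   `voronoi_proportion`, `excess`, `n_obs`, `n_vor`, and the construction.
#' @export
null_comparison <- function(observed, config = run_config(), seeds = NULL) {
  if (is.null(seeds)) {
    seeds <- attr(observed, "seeds")
    if (is.null(seeds)) seeds <- cell_centroids(observed)
  }
  mask <- observed$voxels != 0L
  vor <- voronoi_construct(seeds, mask, observed$spacing)

  obs_m <- measure_scutoids(observed, config)
  sel <- if (config$reuse_band) obs_m$selected else NULL
  vor_m <- measure_scutoids(vor, config, selected = sel)

  structure(list(
    observed_proportion = obs_m$proportion,
    voronoi_proportion = vor_m$proportion,
    excess = obs_m$proportion - vor_m$proportion,
    n_obs = obs_m$n_counted, n_vor = vor_m$n_counted,
    construction = vor), class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(paste0("<null_comparison> observed %.4f (n=%d) vs Voronoi %.4f ",
                     "(n=%d); excess %+.4f\n"),
              x$observed_proportion, x$n_obs, x$voronoi_proportion, x$n_vor,
              x$excess))
  invisible(x)
}

# Single shared measurement path for observed frames and constructions.
measure_scutoids <- function(volume, config, selected = NULL) {
  layers <- extract_layers(volume)
  if (is.null(selected)) selected <- select_band(volume, config$band_depth, layers)
  calls <- detect_scutoids(layers, config, selected)
  list(proportion = scutoid_proportion(calls),
       n_counted = sum(calls$counted), selected = selected,
       calls = calls, layers = layers)
}
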