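# Per-cell and per-region morphometrics: volume, convexity ratio, height,
# density and opening areas.

voxel_indices <- function(volume, label) {
  idx <- which(volume$voxels == label)
  if (!length(idx)) stop("label ", label, " absent from volume")
  d <- dim(volume$voxels)
  k <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  cbind(z = k, y = rest %% d[2] + 1L, x = rest %/% d[2] + 1L)
}

#' Cell volume in cubic micrometres
#'
#' Voxel count times the voxel volume `dz * dy * dx`.
#'
#' @param volume a [label_volume()].
#' @param label cell label (must be present).
#' @return Volume in um^3.
#' @export
cell_volume <- function(volume, label) {
  n <- sum(volume$voxels == label)
  if (n == 0L) stop("label ", label, " absent from volume")
  n * prod(volume$spacing)
}

#' All cell volumes at once
#'
#' @param volume a [label_volume()].
#' @return Data frame `cell_id`, `volume` (um^3) for every label present.
#' @export
cell_volumes <- function(volume) {
  v <- volume$voxels[volume$voxels > 0L]
  tab <- table(v)
  data.frame(cell_id = as.integer(names(tab)),
             volume = as.numeric(tab) * prod(volume$spacing))
}

#' Cell convexity ratio
#'
#' Voxel volume divided by the volume of the convex hull taken over the 8
#' physical corners of every cell voxel. Hull corners (never voxel centres)
#' guarantee hull >= voxel union, so the ratio lies in (0, 1]; axis-aligned
#' cuboids score exactly 1.
#'
#' @param volume a [label_volume()].
#' @param label cell label; the cell must span at least 2 slices and contain
#'   at least 4 non-coplanar voxels.
#' @return Ratio in (0, 1].
#' @export
cell_convexity <- function(volume, label) {
  zyx <- voxel_indices(volume, label)
  if (length(unique(zyx[, 1])) < 2L)
    stop("degenerate cell: spans fewer than 2 slices, convexity undefined")
  pts <- voxel_corner_points(zyx, volume$spacing)
  hull <- convex_hull_volume(pts)
  nrow(zyx) * prod(volume$spacing) / hull
}

#' Cell height
#'
#' 3D Euclidean distance (um) between the centroid of the cell's
#' apical-surface pixels and the centroid of its basal-surface pixels, each
#' taken at its recorded depth.
#'
#' @param volume a [label_volume()].
#' @param layers an [extract_layers()] result for the same volume.
#' @param label cell label; must appear in both layer maps.
#' @return Height in um.
#' @export
cell_height <- function(volume, layers, label) {
  sp <- volume$spacing
  surf_centroid <- function(labmap, depth) {
    w <- which(labmap == label, arr.ind = TRUE)
    if (nrow(w) == 0L)
      stop("label ", label, " missing from a layer map (fully interior cell)")
    z <- depth[w]
    c(x = mean((w[, 2] - 0.5) * sp[3]), y = mean((w[, 1] - 0.5) * sp[2]),
      z = mean((z - 0.5) * sp[1]))
  }
  a <- surf_centroid(layers$apical_labels, layers$apical_depth)
  b <- surf_centroid(layers$basal_labels, layers$basal_depth)
  sqrt(sum((a - b)^2))
}

#' Slope-corrected basal areas per cell
#'
#' The basal footprint pixel count times `dx * dy`, corrected per pixel by
#' the heightfield slope factor `sqrt(1 + (dz/dx)^2 + (dz/dy)^2)` so that the
#' inner basal area of a curved cap is measured on the surface, not on its
#' projection. Flat sheets are unaffected (factor 1).
#'
#' @param layers an [extract_layers()] result.
#' @return Data frame `cell_id`, `basal_area` (um^2).
#' @export
basal_areas <- function(layers) {
  sp <- layers$spacing
  lab <- layers$basal_labels
  zmap <- (layers$basal_depth - 0.5) * sp[1]
  gx <- grad_masked(zmap, lab > 0L, 2, sp[3])
  gy <- grad_masked(zmap, lab > 0L, 1, sp[2])
  fac <- sqrt(1 + gx^2 + gy^2)
  sel <- lab > 0L
  f <- factor(lab[sel])
  area <- tapply(fac[sel], f, sum) * sp[2] * sp[3]
  data.frame(cell_id = as.integer(names(area)), basal_area = as.numeric(area))
}

# central differences of a masked heightfield along margin `along` (1 = rows/y,
# 2 = cols/x); one-sided at mask edges, 0 where no defined neighbour.
grad_masked <- function(zmap, mask, along, step) {
  d <- dim(zmap)
  shift <- function(m, k) {
    out <- matrix(NA_real_, d[1], d[2])
    if (along == 1) {
      if (k > 0) out[(1 + k):d[1], ] <- m[1:(d[1] - k), ]
      else out[1:(d[1] + k), ] <- m[(1 - k):d[1], ]
    } else {
      if (k > 0) out[, (1 + k):d[2]] <- m[, 1:(d[2] - k)]
      else out[, 1:(d[2] + k)] <- m[, (1 - k):d[2]]
    }
    out
  }
  zm <- zmap; zm[!mask] <- NA_real_
  zp <- shift(zm, -1)  # value at +1 position
  zn <- shift(zm, 1)   # value at -1 position
  g <- (zp - zn) / (2 * step)
  one_p <- (zp - zm) / step
  one_n <- (zm - zn) / step
  g[is.na(g)] <- one_p[is.na(g)]
  g[is.na(g)] <- one_n[is.na(g)]
  g[is.na(g)] <- 0
  g[!mask] <- 0
  g
}

#' Cell density of the selected region
#'
#' Number of counted cells divided by the sum of the inner basal areas they
#' occupy (cells per um^2).
#'
#' @param calls a [detect_scutoids()] result.
#' @param records per-cell data frame containing `cell_id` and `basal_area`
#'   (e.g. from [basal_areas()] or the pipeline cell table).
#' @return Density in cells / um^2.
#' @export
cell_density <- function(calls, records) {
  ids <- calls$cell_id[calls$counted]
  if (!length(ids)) stop("no counted cells with basal area")
  ar <- records$basal_area[match(ids, records$cell_id)]
  ar <- ar[!is.na(ar)]
  tot <- sum(ar)
  if (!length(ar) || tot <= 0) stop("zero total basal area")
  length(ar) / tot
}

#' Epithelial opening areas
#'
#' On the full 2D projection of the labels, background connected components
#' lying inside the convex hull of the projected cell footprint are openings;
#' components smaller than `min_opening_area` are dropped. The exterior
#' background (outside the hull) is not an opening.
#'
#' @param volume a [label_volume()].
#' @param min_opening_area smallest reported component (um^2).
#' @return Numeric vector of areas (um^2), with the total as attribute
#'   `"sum"`; empty when the epithelium is sealed.
#' @export
opening_areas <- function(volume, min_opening_area = 5) {
  v <- volume$voxels
  sp <- volume$spacing
  foot <- apply(v != 0L, c(2, 3), any)
  if (!any(foot)) stop("empty volume")
  if (all(foot)) return(structure(numeric(0), sum = 0))
  w <- which(foot, arr.ind = TRUE)
  hull <- grDevices::chull(w[, 2], w[, 1])
  bnd <- cbind(w[hull, 2], w[hull, 1])
  bg <- which(!foot, arr.ind = TRUE)
  inside <- mgcv::in.out(rbind(bnd, bnd[1, ]), cbind(bg[, 2], bg[, 1]))
  open_mask <- matrix(FALSE, nrow(foot), ncol(foot))
  open_mask[bg[inside, , drop = FALSE]] <- TRUE
  if (!any(open_mask)) return(structure(numeric(0), sum = 0))
  comp <- EBImage::bwlabel(open_mask)
  areas <- as.numeric(table(comp[comp > 0])) * sp[2] * sp[3]
  areas <- areas[areas >= min_opening_area]
  structure(sort(areas, decreasing = TRUE), sum = sum(areas))
}
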