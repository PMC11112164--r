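# Apical/basal layer extraction and scutoid detection.
#
# The apical layer of each (x, y) column is the first labelled voxel met when
# scanning z top-down (toward the objective first), the basal layer the first
# met bottom-up. Scutoids are cells whose apical and basal neighbour sets
# differ, the signature of an apico-basal T1 intercalation.

#' Extract apical and basal layer maps by directional z-scans
#'
#' @param volume a [label_volume()] with at least one labelled voxel.
#' @return An object of class `layer_maps`: 2D label maps `apical_labels`,
#'   `basal_labels` and z-index depth maps `apical_depth`, `basal_depth`
#'   (NA where a column contains no cell), plus the volume's spacing.
#' @export
extract_layers <- function(volume) {
  v <- volume$voxels
  d <- dim(v)
  if (!any(v != 0L)) stop("empty volume: no labelled voxels")
  nz <- d[1]
  m <- matrix(v, nrow = nz)                 # columns = (y, x) pairs
  nzro <- m != 0L
  ap <- apply(nzro, 2, function(col) { i <- which(col); if (length(i)) i[1] else NA_integer_ })
  ba <- apply(nzro, 2, function(col) { i <- which(col); if (length(i)) i[length(i)] else NA_integer_ })
  cols <- seq_len(ncol(m))
  pick <- function(depth) {
    lab <- integer(ncol(m))
    ok <- !is.na(depth)
    lab[ok] <- m[cbind(depth[ok], cols[ok])]
    matrix(lab, d[2], d[3])
  }
  structure(list(
    apical_labels = pick(ap), basal_labels = pick(ba),
    apical_depth = matrix(as.numeric(ap), d[2], d[3]),
    basal_depth = matrix(as.numeric(ba), d[2], d[3]),
    spacing = volume$spacing), class = "layer_maps")
}

# offsets of the dilation structuring element: Chebyshev box at radius 1
# (8-connectivity), rounded Euclidean disc beyond.
disc_offsets <- function(radius) {
  g <- expand.grid(di = -radius:radius, dj = -radius:radius)
  g <- g[!(g$di == 0 & g$dj == 0), ]
  if (radius == 1L) return(g)
  g[g$di^2 + g$dj^2 <= radius^2 + radius, ]
}

#' Per-surface neighbour sets by label dilation
#'
#' Each cell's pixel set is dilated by a disc of `dilation_radius`; the
#' labels overlapped by the dilation are its neighbours. At the default
#' radius 1 the element is the 8-connected box, so corner-only contact counts
#' as neighbourhood. The relation is symmetrized by union and is irreflexive;
#' background never appears.
#'
#' @param layer 2D integer label map.
#' @param dilation_radius structuring-element radius in pixels (>= 1).
#' @return Named list mapping each label present to a sorted integer vector
#'   of neighbouring labels (class `neighbour_sets`).
#' @export
neighbour_sets <- function(layer, dilation_radius = 1L) {
  if (dilation_radius < 1) stop("dilation_radius must be >= 1")
  labs <- sort(unique(layer[layer > 0L]))
  nr <- nrow(layer); nc <- ncol(layer)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (r in seq_len(nrow(off <- disc_offsets(as.integer(dilation_radius))))) {
    di <- off$di[r]; dj <- off$dj[r]
    i1 <- max(1L, 1L + di):min(nr, nr + di)
    j1 <- max(1L, 1L + dj):min(nc, nc + dj)
    a <- layer[i1, j1, drop = FALSE]
    b <- layer[i1 - di, j1 - dj, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs_a <- c(pairs_a, a[sel])
      pairs_b <- c(pairs_b, b[sel])
    }
  }
  key <- unique(cbind(pmin(pairs_a, pairs_b), pmax(pairs_a, pairs_b)))
  out <- stats::setNames(rep(list(integer(0)), length(labs)), labs)
  if (nrow(key)) {
    both <- rbind(key, key[, 2:1, drop = FALSE])
    sp <- split(both[, 2], both[, 1])
    for (nm in names(sp)) out[[nm]] <- sort(unique(sp[[nm]]))
  }
  structure(out, class = "neighbour_sets")
}

#' Select the analysis band of cells nearest the objective
#'
#' A cell is selected iff the z-distance (um) from its 3D centroid to the
#' apical surface heightfield at the centroid's (x, y) position is at most
#' `band_depth`, mirroring analysis restricted to the well-imaged cells
#' within a fixed depth of the embryo surface closest to the objective.
#'
#' @param volume a [label_volume()].
#' @param band_depth band depth in um (> 0).
#' @param layers optional precomputed [extract_layers()] result.
#' @return Integer vector of selected labels (empty for an empty volume).
#' @export
select_band <- function(volume, band_depth = 30, layers = NULL) {
  if (band_depth <= 0) stop("band_depth must be > 0")
  if (!any(volume$voxels != 0L)) return(integer(0))
  if (is.null(layers)) layers <- extract_layers(volume)
  sp <- volume$spacing
  cen <- cell_centroids(volume)
  i <- pmin(pmax(round(cen$y / sp[2] + 0.5), 1L), nrow(layers$apical_depth))
  j <- pmin(pmax(round(cen$x / sp[3] + 0.5), 1L), ncol(layers$apical_depth))
  apz <- (layers$apical_depth[cbind(i, j)] - 0.5) * sp[1]
  dist <- cen$z - apz
  sel <- !is.na(dist) & dist <= band_depth
  as.integer(cen$cell_id[sel])
}

#' Call scutoids from apical/basal layer maps
#'
#' For each selected cell the apical and basal neighbour sets are compared;
#' a cell is a scutoid iff the two sets differ. Cells whose apical or basal
#' footprint touches the image boundary are border-flagged; under
#' `border_policy = "exclude"` they are removed from both numerator and
#' denominator of the scutoid proportion (truncated neighbour sets would
#' otherwise inflate it).
#'
#' @param layers an [extract_layers()] result.
#' @param config a [run_config()].
#' @param selected integer vector of selected labels (from [select_band()]).
#' @return Data frame of class `scutoid_calls`: `cell_id`, `is_scutoid`,
#'   `is_border`, `is_selected`, `counted`, and `;`-joined neighbour id
#'   strings `apical_neighbours`, `basal_neighbours`.
#' @export
detect_scutoids <- function(layers, config = run_config(), selected) {
  if (length(selected) == 0L) stop("no selected cells")
  ap <- neighbour_sets(layers$apical_labels, config$dilation_radius)
  ba <- neighbour_sets(layers$basal_labels, config$dilation_radius)
  labs <- sort(unique(c(layers$apical_labels[layers$apical_labels > 0L],
                        layers$basal_labels[layers$basal_labels > 0L])))
  border <- border_labels(layers)
  get <- function(sets, l) {
    s <- sets[[as.character(l)]]
    if (is.null(s)) integer(0) else s
  }
  is_sc <- vapply(labs, function(l) {
    a <- get(ap, l); b <- get(ba, l)
    !(length(a) == length(b) && all(a == b))
  }, logical(1))
  calls <- data.frame(
    cell_id = labs,
    is_scutoid = is_sc,
    is_border = labs %in% border,
    is_selected = labs %in% selected,
    apical_neighbours = vapply(labs, function(l) paste(get(ap, l), collapse = ";"), ""),
    basal_neighbours = vapply(labs, function(l) paste(get(ba, l), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  calls$counted <- calls$is_selected &
    (config$border_policy != "exclude" | !calls$is_border)
  structure(calls, class = c("scutoid_calls", "data.frame"),
            border_policy = config$border_policy)
}

border_labels <- function(layers) {
  edge <- function(m) {
    unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  }
  b <- c(edge(layers$apical_labels), edge(layers$basal_labels))
  sort(unique(b[b > 0L]))
}

#' Proportion of scutoids among counted cells
#'
#' @param calls a [detect_scutoids()] result.
#' @return Fraction in `[0, 1]`: scutoids / counted cells.
#' @export
scutoid_proportion <- function(calls) {
  n <- sum(calls$counted)
  if (n == 0L) stop("zero counted cells")
  sum(calls$is_scutoid & calls$counted) / n
}

#' Normalized depth of the apico-basal transition of a four-cell motif
#'
#' Scans the stack slice by slice, classifying each slice by which of the two
#' opposite pairs of the quartet shares a wall, and returns the normalized z
#' of the deepest slice still in the apical configuration (the flip happens
#' between it and the next slice).
#'
#' @param volume a [label_volume()].
#' @param quartet integer vector of the 4 labels forming the AB-T1.
#' @param dilation_radius radius for the per-slice adjacency (default 1).
#' @return Fraction in (0, 1): flip slice index / n_z.
#' @export
transition_depth <- function(volume, quartet, dilation_radius = 1L) {
  if (length(quartet) != 4L) stop("`quartet` must hold 4 labels")
  v <- volume$voxels
  nz <- dim(v)[1]
  pair_sets <- lapply(seq_len(nz), function(z) {
    m <- v[z, , ]
    m[!(m %in% quartet)] <- 0L
    if (!all(quartet %in% m)) return(NULL)
    ns <- neighbour_sets(m, dilation_radius)
    prs <- list()
    for (a in seq_len(3)) for (b in (a + 1):4) {
      la <- quartet[a]; lb <- quartet[b]
      if (lb %in% ns[[as.character(la)]]) prs <- c(prs, list(c(la, lb)))
    }
    vapply(prs, function(p) paste(sort(p), collapse = "-"), "")
  })
  usable <- which(!vapply(pair_sets, is.null, logical(1)))
  if (length(usable) < 2L) stop("quartet not present across the stack")
  top <- pair_sets[[usable[1]]]
  bot <- pair_sets[[usable[length(usable)]]]
  apical_pair <- setdiff(top, bot)
  basal_pair <- setdiff(bot, top)
  if (length(apical_pair) != 1L || length(basal_pair) != 1L)
    stop("labels are not scutoidal together: no unique neighbour-pair flip")
  state <- vapply(pair_sets[usable], function(s) {
    a <- apical_pair %in% s; b <- basal_pair %in% s
    if (a && !b) 1L else if (b && !a) 2L else NA_integer_
  }, integer(1))
  flip <- max(usable[!is.na(state) & state == 1L])
  flip / nz
}
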