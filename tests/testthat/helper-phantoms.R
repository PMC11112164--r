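# Shared fixture builders (all generated in code; no stored data).

hemi_spec <- function(n_cells = 150, rng_seed = 5, spacing = c(1, 1, 1),
                      outer = c(45, 45, 45), inner = c(33, 33, 33),
                      jitter = 1.5, ...) {
  phantom_spec(outer, inner, n_cells, spacing = spacing, jitter = jitter,
               rng_seed = rng_seed, view_halfangle = pi / 2, ...)
}

# a solid ellipsoid volume labelled 1 (for axes/mask tests)
solid_ellipsoid_volume <- function(semiaxes, spacing = c(1, 1, 1)) {
  spec <- phantom_spec(semiaxes, c(1e-9, 1e-9, 1e-9), 4, spacing = spacing)
  m <- make_shell_mask(spec)
  label_volume(array(as.integer(m), dim(m)), spacing)
}

# axis-aligned cuboid cell inside background
cuboid_volume <- function(zr = 2:9, yr = 3:10, xr = 3:10, dims = c(10, 12, 14),
                          spacing = c(1, 1, 1), label = 1L) {
  v <- array(0L, dims)
  v[zr, yr, xr] <- label
  label_volume(v, spacing)
}

# brute-force 2D neighbour oracle: labels a, b are neighbours iff some pixel
# of a and some pixel of b are within Chebyshev distance `radius`
oracle_neighbours <- function(layer, radius = 1L) {
  labs <- sort(unique(layer[layer > 0L]))
  px <- lapply(labs, function(l) which(layer == l, arr.ind = TRUE))
  names(px) <- labs
  out <- stats::setNames(rep(list(integer(0)), length(labs)), labs)
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (a == b) next
    pa <- px[[a]]; pb <- px[[b]]
    dd <- outer(pa[, 1], pb[, 1], function(u, v) abs(u - v))
    ee <- outer(pa[, 2], pb[, 2], function(u, v) abs(u - v))
    if (min(pmax(dd, ee)) <= radius)
      out[[as.character(labs[a])]] <- c(out[[as.character(labs[a])]], labs[b])
  }
  lapply(out, function(s) sort(unique(s)))
}

# brute-force nearest-seed oracle over a full grid
oracle_voronoi <- function(seeds, dims, spacing) {
  axz <- (seq_len(dims[1]) - 0.5) * spacing[1]
  axy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  axx <- (seq_len(dims[3]) - 0.5) * spacing[3]
  arr <- array(0L, dims)
  for (k in seq_len(dims[1])) for (i in seq_len(dims[2])) for (j in seq_len(dims[3])) {
    d2 <- (seeds$x - axx[j])^2 + (seeds$y - axy[i])^2 + (seeds$z - axz[k])^2
    arr[k, i, j] <- seeds$cell_id[which.min(d2)]
  }
  arr
}

measure_prop <- function(volume, config = run_config()) {
  layers <- extract_layers(volume)
  sel <- select_band(volume, config$band_depth, layers)
  scutoid_proportion(detect_scutoids(layers, config, sel))
}
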