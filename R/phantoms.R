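# Synthetic spheroidal-epithelium phantoms with known ground truth.
#
# The generators emulate a monolayered blastula-like epithelium: cells are
# Voronoi regions of quasi-uniform seeds on the mid-surface of an ellipsoidal
# shell, optionally restricted to the imaged cap nearest the objective,
# optionally perforated by openings, and optionally advanced through
# synchronous division waves. They are geometric, not biophysical.

#' Specification of a spheroidal shell phantom
#'
#' @param outer_semiaxes,inner_semiaxes ellipsoid semi-axes `c(ax, ay, az)`
#'   in um; inner must be componentwise smaller than outer.
#' @param n_cells number of seeds/cells (>= 4).
#' @param spacing voxel spacing `c(dz, dy, dx)` in um, all > 0.
#' @param shape voxel grid dimensions `c(nz, ny, nx)`; computed from the
#'   outer ellipsoid plus a 3-voxel margin when `NULL`.
#' @param jitter standard deviation (um) of Gaussian noise added to the
#'   quasi-uniform seed positions.
#' @param opening_caps list of `list(direction = c(x, y, z), angular_radius)`
#'   caps cleared to background after labelling (see [inject_opening()]).
#' @param rng_seed integer seed making the phantom bit-reproducible.
#' @param view_halfangle angular radius (rad) of the imaged cap about the
#'   axis pointing toward the objective (low z). `pi` (default) keeps the
#'   full shell; `pi / 2` keeps the hemisphere nearest the objective, which
#'   is the geometry an objective-side confocal stack actually captures.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semiaxes, inner_semiaxes, n_cells,
                         spacing = c(1.5, 1.5, 1.5), shape = NULL,
                         jitter = 1.5, opening_caps = list(),
                         rng_seed = 1L, view_halfangle = pi) {
  stopifnot(length(outer_semiaxes) == 3, length(inner_semiaxes) == 3,
            length(spacing) == 3)
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  if (any(inner_semiaxes < 0) || any(outer_semiaxes <= 0))
    stop("semi-axes must be non-negative (outer strictly positive)")
  if (any(inner_semiaxes >= outer_semiaxes))
    stop("inner_semiaxes must be componentwise < outer_semiaxes")
  if (n_cells < 4) stop("n_cells must be >= 4")
  if (view_halfangle <= 0 || view_halfangle > pi)
    stop("view_halfangle must be in (0, pi]")
  if (is.null(shape)) {
    # margin of 3 voxels per side; axis order (z, y, x) vs semiaxes (x, y, z)
    shape <- ceiling(2 * outer_semiaxes[c(3, 2, 1)] / spacing) + 6L
  }
  structure(list(outer_semiaxes = as.numeric(outer_semiaxes),
                 inner_semiaxes = as.numeric(inner_semiaxes),
                 n_cells = as.integer(n_cells), spacing = as.numeric(spacing),
                 shape = as.integer(shape), jitter = jitter,
                 opening_caps = opening_caps, rng_seed = as.integer(rng_seed),
                 view_halfangle = view_halfangle),
            class = "phantom_spec")
}

phantom_centre <- function(spec) {
  # physical centre (x, y, z) of the grid
  c(spec$shape[3] * spec$spacing[3], spec$shape[2] * spec$spacing[2],
    spec$shape[1] * spec$spacing[1]) / 2
}

#' Binary mask of an ellipsoidal shell (optionally an imaged cap)
#'
#' A voxel belongs to the mask iff its physical centre lies inside the outer
#' ellipsoid, outside the inner ellipsoid and, when `view_halfangle < pi`,
#' within the viewing cone about the objective-facing axis.
#'
#' @param spec a [phantom_spec()].
#' @return 3D logical array `(z, y, x)`.
#' @export
make_shell_mask <- function(spec) {
  thick <- spec$outer_semiaxes - spec$inner_semiaxes       # (x, y, z)
  if (any(thick < spec$spacing[c(3, 2, 1)]))
    stop("degenerate shell: thinner than one voxel along some axis")
  d <- spec$shape
  cc <- phantom_centre(spec)                               # (x, y, z)
  ax <- voxel_axes(list(voxels = array(0L, d), spacing = spec$spacing))
  xd <- ax$x - cc[1]; yd <- ax$y - cc[2]; zd <- ax$z - cc[3]
  qsum <- function(a) {  # [z, y, x] array of sum_i (delta_i / a_i)^2
    outer(outer((zd / a[3])^2, (yd / a[2])^2, "+"), (xd / a[1])^2, "+")
  }
  inside_outer <- qsum(spec$outer_semiaxes) <= 1
  if (all(spec$inner_semiaxes == 0)) {
    mask <- inside_outer
  } else {
    a_in <- pmax(spec$inner_semiaxes, 1e-9)
    mask <- inside_outer & (qsum(a_in) > 1)
  }
  if (spec$view_halfangle < pi) {
    r2 <- outer(outer(zd^2, yd^2, "+"), xd^2, "+")
    # objective-facing axis is (0, 0, -1): cos(angle) = -dz / r
    zarr <- array(rep(zd, times = d[2] * d[3]), dim = d)
    keep <- -zarr >= cos(spec$view_halfangle) * sqrt(r2)
    mask <- mask & keep
  }
  mask
}

# Quasi-uniform directions on the unit sphere cap about axis (0, 0, -1):
# golden-angle spiral restricted to polar angles <= halfangle.
spiral_directions <- function(n, halfangle) {
  k <- seq_len(n)
  t <- 1 - (k - 0.5) / n * (1 - cos(halfangle))   # cos(polar angle) in axis frame
  phi <- k * pi * (3 - sqrt(5))                   # golden angle
  s <- sqrt(pmax(0, 1 - t^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = -t)
}

#' Generate a labelled Voronoi epithelium on a shell phantom
#'
#' Seeds are placed on the mid-surface ellipsoid by a deterministic
#' golden-angle spiral (quasi-uniform density, like the embryo's epithelium)
#' plus Gaussian jitter, then every mask voxel is assigned to its nearest
#' seed in physical distance. Labels are `1..n_cells`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [label_volume()]) and `seeds` (data frame
#'   `cell_id, x, y, z`).
#' @export
make_voronoi_epithelium <- function(spec) {
  mask <- make_shell_mask(spec)
  if (spec$n_cells > sum(mask))
    stop("n_cells exceeds the number of mask voxels")
  set.seed(spec$rng_seed)
  seeds <- phantom_seeds(spec)
  vol <- suppressWarnings(voronoi_construct(seeds, mask, spec$spacing))
  vol <- as_plain_volume(vol)
  attr(vol, "centre") <- phantom_centre(spec)
  for (cap in spec$opening_caps)
    vol <- inject_opening(vol, cap$direction, cap$angular_radius)
  list(volume = vol, seeds = seeds)
}

phantom_seeds <- function(spec, n = spec$n_cells) {
  mid <- (spec$outer_semiaxes + spec$inner_semiaxes) / 2
  cc <- phantom_centre(spec)
  dirs <- spiral_directions(n, spec$view_halfangle)
  pts <- dirs %*% diag(mid)
  if (spec$jitter > 0) {
    # jitter tangentially: a monolayer keeps its cells on the mid-surface,
    # so seed-position noise perturbs positions within the surface, not
    # radially off it
    g <- matrix(stats::rnorm(3 * n, sd = spec$jitter), ncol = 3)
    nrm <- pts %*% diag(1 / mid^2)           # ellipsoid surface normal
    nrm <- nrm / sqrt(rowSums(nrm^2))
    g <- g - nrm * rowSums(g * nrm)
    pts <- pts + g
    # re-project onto the mid-surface ellipsoid
    s <- sqrt((pts[, 1] / mid[1])^2 + (pts[, 2] / mid[2])^2 +
                (pts[, 3] / mid[3])^2)
    pts <- pts / s
  }
  pts <- sweep(pts, 2, cc, "+")
  data.frame(cell_id = seq_len(n), x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

# drop the voronoi_construction class/seed attribute: phantom volumes play
# the role of observed frames, whose null model must be rebuilt from cell
# centroids, not from the generating seeds.
as_plain_volume <- function(vol) {
  attr(vol, "seeds") <- NULL
  class(vol) <- "label_volume"
  vol
}

#' Rectangular prism lattice (zero-scutoid ground truth)
#'
#' `n_x * n_y` rectangular columns, each a constant label through every z
#' slice; prisms have identical apical and basal neighbour sets, so the
#' lattice contains no scutoids by construction.
#'
#' @param n_x,n_y number of columns along x and y (>= 1).
#' @param cell_xy lateral cell size (um).
#' @param height slab height (um).
#' @param spacing voxel spacing `c(dz, dy, dx)` um.
#' @return A [label_volume()].
#' @export
make_prism_lattice <- function(n_x, n_y, cell_xy = 8, height = 12,
                               spacing = c(1, 1, 1)) {
  if (n_x < 1 || n_y < 1) stop("counts must be >= 1")
  px <- max(1L, round(cell_xy / spacing[3]))
  py <- max(1L, round(cell_xy / spacing[2]))
  nz <- max(1L, round(height / spacing[1]))
  iy <- rep(seq_len(n_y), each = py)
  ix <- rep(seq_len(n_x), each = px)
  lab2d <- outer(iy, ix, function(a, b) (a - 1L) * n_x + b)
  vox <- array(rep(as.integer(lab2d), each = nz),
               dim = c(nz, length(iy), length(ix)))
  label_volume(vox, spacing)
}

#' Four-cell scutoid motif with a controlled apico-basal transition
#'
#' Builds a 2 x 2 block of columns A, B, C, D (labels 1, 2, 3, 4) inside a
#' 2-pixel background margin. Above the transition slice the central wall
#' joins A and B (C, D separated); below it, C and D are joined (A, B
#' separated), so all four cells are scutoids and the neighbour-pair flip
#' sits at `round(transition_frac * n_z)`. The joined pair always shares a
#' 2-pixel wall whose anti-diagonal placement keeps the separated pair at
#' Chebyshev distance 2, so corner contact never bridges it.
#'
#' @param transition_frac flip position as a fraction of the stack height,
#'   strictly inside (0, 1).
#' @param cell_xy lateral cell size (um).
#' @param height stack height (um).
#' @param spacing voxel spacing `c(dz, dy, dx)` um.
#' @return A [label_volume()] with labels A=1, B=2, C=3, D=4.
#' @export
make_scutoid_quartet <- function(transition_frac, cell_xy = 8, height = 12,
                                 spacing = c(1, 1, 1)) {
  if (!is.finite(transition_frac) || transition_frac <= 0 || transition_frac >= 1)
    stop("transition_frac must be strictly inside (0, 1)")
  nz <- round(height / spacing[1])
  if (nz < 3) stop("n_z < 3: no room for an apico-basal transition")
  k <- round(transition_frac * nz)
  if (k < 1 || k > nz - 1)
    stop("transition slice falls outside the stack; use a less extreme fraction")
  m <- max(2L, round(cell_xy / spacing[3]))
  base <- matrix(0L, 2 * m, 2 * m)
  base[seq_len(m), seq_len(m)] <- 1L                    # A
  base[m + seq_len(m), m + seq_len(m)] <- 2L            # B
  base[seq_len(m), m + seq_len(m)] <- 3L                # C
  base[m + seq_len(m), seq_len(m)] <- 4L                # D
  apical <- base; apical[m, m + 1L] <- 1L; apical[m + 1L, m] <- 2L
  basal <- base;  basal[m, m] <- 3L;       basal[m + 1L, m + 1L] <- 4L
  pad <- function(mat) {
    out <- matrix(0L, nrow(mat) + 4L, ncol(mat) + 4L)
    out[2L + seq_len(nrow(mat)), 2L + seq_len(ncol(mat))] <- mat
    out
  }
  apical <- pad(apical); basal <- pad(basal)
  vox <- array(0L, dim = c(nz, nrow(apical), ncol(apical)))
  for (z in seq_len(nz)) vox[z, , ] <- if (z <= k) apical else basal
  label_volume(vox, spacing)
}

#' Clear an angular cap of cells to background (an epithelial opening)
#'
#' Labels whose centroid direction from the ellipsoid centre lies within
#' `angular_radius` of `direction` are removed, mimicking the openings that
#' close progressively during epithelial sealing.
#'
#' @param volume a [label_volume()] from a spheroidal phantom (the centre is
#'   taken from its `"centre"` attribute, else the grid centre).
#' @param direction cap axis `c(x, y, z)` (need not be unit length).
#' @param angular_radius cap angular radius in radians; `<= 0` warns and
#'   returns the volume unchanged.
#' @return The modified [label_volume()].
#' @export
inject_opening <- function(volume, direction, angular_radius) {
  if (angular_radius <= 0) {
    warning("angular_radius <= 0: no-op")
    return(volume)
  }
  cc <- attr(volume, "centre")
  if (is.null(cc)) {
    d <- dim(volume$voxels)
    cc <- c(d[3] * volume$spacing[3], d[2] * volume$spacing[2],
            d[1] * volume$spacing[1]) / 2
  }
  u <- direction / sqrt(sum(direction^2))
  cen <- cell_centroids(volume)
  rel <- cbind(cen$x - cc[1], cen$y - cc[2], cen$z - cc[3])
  r <- sqrt(rowSums(rel^2))
  cosang <- as.numeric(rel %*% u) / pmax(r, .Machine$double.eps)
  drop <- cen$cell_id[cosang >= cos(angular_radius)]
  if (length(drop)) volume$voxels[volume$voxels %in% drop] <- 0L
  volume
}

#' Specification of a simulated division time-lapse
#'
#' @param base a [phantom_spec()] for the initial frame.
#' @param n_frames number of frames (1-based; frame 1 is the initial state).
#' @param division_frames named list mapping frame numbers (as names) to
#'   vectors of dividing cell ids, or the string `"all"` for a synchronous
#'   wave. Frames must lie in `[2, n_frames]`.
#' @param displacement daughter-seed separation in um (daughters sit at
#'   `+/- displacement / 2` along a random tangent of the mid-surface).
#' @return An object of class `timelapse_spec`.
#' @export
timelapse_spec <- function(base, n_frames, division_frames = list(),
                           displacement = 4) {
  stopifnot(inherits(base, "phantom_spec"))
  fr <- as.integer(names(division_frames))
  if (length(division_frames) && (anyNA(fr) || any(fr < 2L | fr > n_frames)))
    stop("division frames must be integers in [2, n_frames]")
  structure(list(base = base, n_frames = as.integer(n_frames),
                 division_frames = division_frames,
                 displacement = displacement),
            class = "timelapse_spec")
}

#' Simulate a time-lapse of synchronous division waves
#'
#' At each division frame every dividing seed is replaced by two daughter
#' seeds offset by `+/- displacement / 2` along a random tangent direction,
#' and the Voronoi epithelium is regenerated on the same shell mask. The
#' event table records lineage and per-cell interphase bounds (the frame a
#' cell appears at, to the frame it divides; cells that never divide are
#' right-censored at the last frame).
#'
#' @param tspec a [timelapse_spec()].
#' @return List with `volumes` (list of [label_volume()], persistent labels),
#'   `events` (data frame `cell_id, parent_id, division_frame,
#'   interphase_start, interphase_end, censored`) and `mask`.
#' @export
simulate_division_series <- function(tspec) {
  spec <- tspec$base
  mask <- make_shell_mask(spec)
  set.seed(spec$rng_seed)
  seeds <- phantom_seeds(spec)
  cc <- phantom_centre(spec)
  mid <- (spec$outer_semiaxes + spec$inner_semiaxes) / 2
  # local cell diameter estimate on the mid-surface (sphere-equivalent)
  events <- data.frame(cell_id = seeds$cell_id, parent_id = NA_integer_,
                       division_frame = NA_integer_, interphase_start = 1L,
                       interphase_end = NA_integer_)
  volumes <- vector("list", tspec$n_frames)
  for (f in seq_len(tspec$n_frames)) {
    div <- tspec$division_frames[[as.character(f)]]
    if (!is.null(div)) {
      if (identical(div, "all")) div <- seeds$cell_id
      local_diam <- 2 * sqrt(4 * pi * prod(mid)^(2 / 3) / nrow(seeds) / pi)
      if (tspec$displacement > local_diam)
        warning("displacement exceeds the local cell diameter at frame ", f)
      for (p in div) {
        row <- which(seeds$cell_id == p)
        if (!length(row)) stop("dividing cell ", p, " not present at frame ", f)
        s <- as.numeric(seeds[row, c("x", "y", "z")])
        radial <- (s - cc) / sqrt(sum((s - cc)^2))
        rnd <- stats::rnorm(3)
        tang <- crossprod3(radial, rnd)
        tang <- tang / sqrt(sum(tang^2))
        off <- tang * tspec$displacement / 2
        ids <- max(events$cell_id) + 1:2
        seeds <- rbind(seeds[-row, ],
                       data.frame(cell_id = ids,
                                  x = s[1] + c(1, -1) * off[1],
                                  y = s[2] + c(1, -1) * off[2],
                                  z = s[3] + c(1, -1) * off[3]))
        events$interphase_end[events$cell_id == p] <- f
        events <- rbind(events,
                        data.frame(cell_id = ids, parent_id = p,
                                   division_frame = f, interphase_start = f,
                                   interphase_end = NA_integer_))
      }
    }
    vol <- suppressWarnings(voronoi_construct(seeds, mask, spec$spacing))
    vol <- as_plain_volume(vol)
    vol$frame_index <- f
    attr(vol, "centre") <- cc
    volumes[[f]] <- vol
  }
  events$censored <- is.na(events$interphase_end)
  events$interphase_end[events$censored] <- tspec$n_frames
  list(volumes = volumes, events = events, mask = mask)
}

#' Sample synthetic normalized scutoid onset times
#'
#' A fraction `p_after` of onsets is uniform on `[0, threshold)` (after
#' mitosis), the rest uniform on `[threshold, 1)` (independent of mitosis).
#'
#' @param n number of onsets (>= 1).
#' @param p_after probability of the after-mitosis class.
#' @param threshold interphase fraction separating the classes.
#' @param rng_seed optional integer seed.
#' @return Numeric vector of normalized onsets in `[0, 1)`.
#' @export
sample_onset_times <- function(n, p_after, threshold = 0.15, rng_seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (p_after < 0 || p_after > 1) stop("p_after must be in [0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  after <- stats::runif(n) < p_after
  ifelse(after, stats::runif(n) * threshold,
         threshold + stats::runif(n) * (1 - threshold))
}
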