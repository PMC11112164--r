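test_that("shell mask voxel count matches the analytic shell volume", {
  spec <- phantom_spec(c(50, 50, 50), c(40, 40, 40), 10, spacing = c(1, 1, 1))
  m <- make_shell_mask(spec)
  analytic <- 4 / 3 * pi * (50^3 - 40^3)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.03)
})

test_that("near-zero inner semi-axes give a solid ellipsoid mask", {
  spec <- phantom_spec(c(20, 20, 20), c(1e-9, 1e-9, 1e-9), 4, spacing = c(1, 1, 1))
  m <- make_shell_mask(spec)
  analytic <- 4 / 3 * pi * 20^3
  expect_lt(abs(sum(m) - analytic) / analytic, 0.03)
})

test_that("a shell thinner than one voxel is rejected as degenerate", {
  expect_error(phantom_spec(c(50, 50, 50), c(50, 50, 50), 10),
               "componentwise")
  spec <- phantom_spec(c(50, 50, 50), c(49.5, 49.5, 49.5), 10,
                       spacing = c(1, 1, 1))
  expect_error(make_shell_mask(spec), "degenerate shell")
})

test_that("the epithelium generator is bit-reproducible and partitions its mask", {
  spec <- hemi_spec(n_cells = 60, rng_seed = 21, spacing = c(1.5, 1.5, 1.5))
  a <- make_voronoi_epithelium(spec)
  b <- make_voronoi_epithelium(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$seeds, b$seeds)
  mask <- make_shell_mask(spec)
  expect_identical(a$volume$voxels != 0L, mask)        # exact partition
  expect_setequal(volume_labels(a$volume), 1:60)       # every label occupied
})

test_that("every label survives on a dense 128^3-grid instance", {
  spec <- phantom_spec(c(55, 55, 55), c(43, 43, 43), 500,
                       spacing = c(1, 1, 1), shape = c(128, 128, 128),
                       jitter = 1.5, rng_seed = 9)
  ep <- make_voronoi_epithelium(spec)
  expect_setequal(volume_labels(ep$volume), 1:500)
})

test_that("n_cells exceeding the mask size is an error", {
  spec <- phantom_spec(c(6, 6, 6), c(4, 4, 4), 4000, spacing = c(1, 1, 1))
  expect_error(make_voronoi_epithelium(spec), "exceeds")
})

test_that("prism lattice is labelled by construction", {
  p <- make_prism_lattice(3, 3, cell_xy = 4, height = 6)
  expect_setequal(volume_labels(p), 1:9)
  # all slices identical columns
  expect_true(all(apply(p$voxels, c(2, 3), function(col) length(unique(col)) == 1)))
  ns <- neighbour_sets(extract_layers(p)$apical_labels, 1L)
  expect_setequal(ns[["5"]], c(1, 2, 3, 4, 6, 7, 8, 9))  # centre cell, 8-connectivity
  single <- make_prism_lattice(1, 1, cell_xy = 4, height = 6)
  expect_identical(neighbour_sets(extract_layers(single)$apical_labels)[["1"]],
                   integer(0))
})

test_that("quartet generator needs room for a transition", {
  expect_error(make_scutoid_quartet(0), "strictly inside")
  expect_error(make_scutoid_quartet(1), "strictly inside")
  expect_error(make_scutoid_quartet(0.5, height = 2, spacing = c(1, 1, 1)),
               "n_z < 3")
  expect_error(make_scutoid_quartet(0.01, height = 10, spacing = c(1, 1, 1)),
               "outside the stack")
})

test_that("injected openings remove a cap of cells and are detected", {
  spec0 <- hemi_spec(n_cells = 150)
  ep0 <- make_voronoi_epithelium(spec0)
  ep1 <- inject_opening(ep0$volume, c(0, 0, -1), 0.3)
  expect_lt(length(volume_labels(ep1)), 150)
  op <- opening_areas(ep1, min_opening_area = 5)
  expect_gt(attr(op, "sum"), 0)
  # oracle: area of footprint coverage lost to the cap removal
  lost <- apply(ep0$volume$voxels != 0L, c(2, 3), any) &
    !apply(ep1$voxels != 0L, c(2, 3), any)
  expect_lt(abs(attr(op, "sum") - sum(lost)) / sum(lost), 0.05)
  # two disjoint caps give two components
  ep2 <- inject_opening(ep0$volume, c(0, 0, -1), 0.25)
  ep2 <- inject_opening(ep2, c(1, 0, -1) / sqrt(2), 0.2)
  expect_gte(length(opening_areas(ep2, min_opening_area = 5)), 2)
  expect_warning(inject_opening(ep0$volume, c(0, 0, -1), 0), "no-op")
})

test_that("division series conserves geometry and reports lineage", {
  base <- hemi_spec(n_cells = 30, rng_seed = 13, spacing = c(1.5, 1.5, 1.5))
  ts <- timelapse_spec(base, n_frames = 3, division_frames = list(`2` = c(4L, 9L)))
  sim <- simulate_division_series(ts)
  expect_length(sim$volumes, 3)
  # two divisions: label count rises by exactly 2
  expect_identical(length(volume_labels(sim$volumes[[2]])),
                   length(volume_labels(sim$volumes[[1]])) + 2L)
  # daughters' summed volume close to parent volume at the division frame
  for (p in c(4L, 9L)) {
    kids <- sim$events$cell_id[!is.na(sim$events$parent_id) & sim$events$parent_id == p]
    vol_parent <- cell_volume(sim$volumes[[1]], p)
    vol_kids <- sum(vapply(kids, function(k) cell_volume(sim$volumes[[2]], k), 1))
    expect_lt(abs(vol_kids - vol_parent) / vol_parent, 0.15)
  }
  # fixed seed: identical event tables
  sim2 <- simulate_division_series(ts)
  expect_identical(sim$events, sim2$events)
  expect_identical(sim$volumes[[3]]$voxels, sim2$volumes[[3]]$voxels)
})

test_that("onset sampler respects its class boundaries", {
  expect_error(sample_onset_times(0, 0.5), ">= 1")
  expect_true(all(sample_onset_times(200, 1, 0.15, rng_seed = 1) < 0.15))
  expect_true(all(sample_onset_times(200, 0, 0.15, rng_seed = 1) >= 0.15))
})
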