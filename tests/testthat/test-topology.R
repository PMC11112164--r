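test_that("layer extraction picks first labelled voxels from either end", {
  p <- make_prism_lattice(2, 2, cell_xy = 3, height = 5)
  ly <- extract_layers(p)
  expect_identical(ly$apical_labels, ly$basal_labels)
  expect_true(all(ly$apical_depth == 1))
  expect_true(all(ly$basal_depth == 5))
  # background-only columns are 0 / NA
  v <- p$voxels
  arr <- array(0L, dim(v) + c(0L, 2L, 2L))
  arr[, seq_len(dim(v)[2]), seq_len(dim(v)[3])] <- v
  ly2 <- extract_layers(label_volume(arr, p$spacing))
  expect_identical(ly2$apical_labels[7, 8], 0L)
  expect_true(is.na(ly2$apical_depth[7, 8]))
  expect_error(extract_layers(label_volume(array(0L, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
})

test_that("quartet layer maps show the apical A-B and basal C-D walls", {
  q <- make_scutoid_quartet(0.5, cell_xy = 6, height = 10)
  ly <- extract_layers(q)
  apn <- neighbour_sets(ly$apical_labels)
  ban <- neighbour_sets(ly$basal_labels)
  expect_setequal(apn[["1"]], c(2, 3, 4))  # A joined to B apically
  expect_setequal(apn[["3"]], c(1, 2))     # C and D separated apically
  expect_setequal(ban[["3"]], c(1, 2, 4))  # C joined to D basally
  expect_setequal(ban[["1"]], c(3, 4))     # A and B separated basally
})

test_that("neighbour sets match the exhaustive pixel-adjacency oracle", {
  set.seed(7)
  ep <- make_voronoi_epithelium(hemi_spec(n_cells = 40, rng_seed = 4,
                                          spacing = c(1.5, 1.5, 1.5)))
  for (side in c("apical_labels", "basal_labels")) {
    layer <- extract_layers(ep$volume)[[side]]
    got <- neighbour_sets(layer, 1L)
    want <- oracle_neighbours(layer, 1L)
    expect_identical(lapply(got, as.integer), lapply(want, as.integer))
  }
})

test_that("the neighbour relation is symmetric and irreflexive", {
  ep <- make_voronoi_epithelium(hemi_spec(n_cells = 80, rng_seed = 31))
  ns <- neighbour_sets(extract_layers(ep$volume)$apical_labels, 1L)
  for (nm in names(ns)) {
    l <- as.integer(nm)
    expect_false(l %in% ns[[nm]])
    expect_false(0L %in% ns[[nm]])
    for (nb in ns[[nm]]) expect_true(l %in% ns[[as.character(nb)]])
  }
})

test_that("band selection keeps only cells near the apical surface", {
  # two stacked slabs sharing columns: upper in z 1..5, lower in z 6..20
  arr <- array(0L, c(20, 8, 8))
  lab2d <- outer(rep(1:2, each = 4), rep(1:2, each = 4),
                 function(a, b) (a - 1L) * 2L + b)
  for (z in 1:5) arr[z, , ] <- lab2d
  for (z in 6:20) arr[z, , ] <- lab2d + 4L
  vol <- label_volume(arr, c(1, 1, 1))
  sel <- select_band(vol, band_depth = 5)
  expect_setequal(sel, 1:4)
  expect_setequal(select_band(vol, band_depth = 100), 1:8)
  expect_error(select_band(vol, band_depth = 0), "> 0")
})

test_that("scutoid detection: prisms score 0, the quartet scores 4/4", {
  p <- make_prism_lattice(4, 4, cell_xy = 4, height = 6)
  cfg <- run_config()
  calls_p <- detect_scutoids(extract_layers(p), cfg, select_band(p, 100))
  expect_identical(sum(calls_p$is_scutoid & calls_p$counted), 0L)
  expect_equal(scutoid_proportion(calls_p), 0)

  q <- make_scutoid_quartet(0.5, cell_xy = 6, height = 10)
  calls_q <- detect_scutoids(extract_layers(q), cfg, select_band(q, 100))
  expect_identical(sum(calls_q$is_scutoid), 4L)
  expect_equal(scutoid_proportion(calls_q), 1)
})

test_that("border policy removes boundary cells from both sides of the ratio", {
  # quartet occupies the full image: all 4 cells touch the boundary
  q <- make_scutoid_quartet(0.5, cell_xy = 6, height = 10)
  trimmed <- label_volume(q$voxels[, 3:14, 3:14], q$spacing)
  ly <- extract_layers(trimmed)
  sel <- select_band(trimmed, 100)
  expect_error(detect_scutoids(ly, run_config(border_policy = "exclude"), sel) |>
                 scutoid_proportion(), "zero counted")
  calls <- detect_scutoids(ly, run_config(border_policy = "include-flagged"), sel)
  expect_true(all(calls$is_border))
  expect_equal(scutoid_proportion(calls), 1)
})

test_that("a quartet embedded in a prism ring gives proportion 4/12", {
  q <- make_scutoid_quartet(0.5, cell_xy = 4, height = 8)
  core <- q$voxels[, 3:10, 3:10]           # strip the background margin
  nz <- dim(core)[1]
  ring <- array(0L, c(nz, 24, 24))
  lab2d <- outer(rep(1:3, each = 8), rep(1:3, each = 8),
                 function(a, b) 4L + (a - 1L) * 3L + b)
  for (z in seq_len(nz)) ring[z, , ] <- lab2d
  ring[, 9:16, 9:16] <- core                # centre block replaced by quartet
  vol <- label_volume(ring, c(1, 1, 1))
  cfg <- run_config(border_policy = "include-flagged")
  calls <- detect_scutoids(extract_layers(vol), cfg, select_band(vol, 100))
  expect_identical(sum(calls$counted), 12L)
  expect_equal(scutoid_proportion(calls), 4 / 12)
})

test_that("scutoid calls are invariant under label permutation", {
  ep <- make_voronoi_epithelium(hemi_spec(n_cells = 50, rng_seed = 8,
                                          spacing = c(1.5, 1.5, 1.5)))
  v <- ep$volume
  set.seed(1)
  perm <- sample(50)
  v2 <- v
  v2$voxels[v$voxels > 0L] <- perm[v$voxels[v$voxels > 0L]]
  cfg <- run_config()
  c1 <- detect_scutoids(extract_layers(v), cfg, select_band(v, 30))
  c2 <- detect_scutoids(extract_layers(v2), cfg, select_band(v2, 30))
  m <- match(perm[c1$cell_id], c2$cell_id)
  expect_identical(c1$is_scutoid, c2$is_scutoid[m])
  expect_identical(c1$counted, c2$counted[m])
})

test_that("transition depth recovers the constructed flip position", {
  for (f in c(0.2, 0.5, 0.8)) {
    q <- make_scutoid_quartet(f, cell_xy = 6, height = 20, spacing = c(1, 1, 1))
    nz <- dim(q$voxels)[1]
    expect_lte(abs(transition_depth(q, 1:4) - f), 1 / nz + 1e-9)
  }
  p <- make_prism_lattice(2, 2, cell_xy = 6, height = 10)
  expect_error(transition_depth(p, 1:4), "not scutoidal")
})
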