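sphere_points <- function(R = 50, a = NULL, n_th = 25, n_ph = 48) {
  if (is.null(a)) a <- c(R, R, R)
  th <- seq(0.05, pi - 0.05, length.out = n_th)
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[-1]
  g <- expand.grid(th = th, ph = ph)
  cbind(x = a[1] * sin(g$th) * cos(g$ph), y = a[2] * sin(g$th) * sin(g$ph),
        z = a[3] * cos(g$th))
}

test_that("exact quadric samples are recovered by the ellipsoid fit", {
  f1 <- fit_ellipsoid(sphere_points(50))
  expect_equal(f1$semiaxes, c(50, 50, 50), tolerance = 1e-6)
  expect_lt(f1$residual, 1e-6)
  f2 <- fit_ellipsoid(sphere_points(a = c(60, 60, 40)))
  expect_equal(sort(f2$semiaxes), c(40, 60, 60), tolerance = 1e-4)
  # rotated + translated ellipsoid
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  p <- sweep(sphere_points(a = c(55, 45, 35)) %*% t(Rz), 2, c(10, -20, 5), "+")
  f3 <- fit_ellipsoid(p)
  expect_equal(f3$centre, c(10, -20, 5), tolerance = 1e-6)
  expect_equal(f3$semiaxes, c(55, 45, 35), tolerance = 1e-4)
  expect_error(fit_ellipsoid(sphere_points(50)[1:5, ]), ">= 9")
  flat <- cbind(runif(30), runif(30), 0)
  expect_error(fit_ellipsoid(flat), "ellipsoid|degenerate")
})

test_that("principal curvatures match the closed-form ellipsoid values", {
  fit <- fit_ellipsoid(sphere_points(a = c(60, 60, 40)))
  a <- 60; c_ <- 40
  pole <- principal_curvatures(fit, c(0, 0, 40))
  expect_equal(unname(pole), c(c_ / a^2, c_ / a^2), tolerance = 1e-6)
  eq <- principal_curvatures(fit, c(60, 0, 0))
  expect_equal(unname(eq), c(a / c_^2, 1 / a), tolerance = 1e-6)
  sph <- fit_ellipsoid(sphere_points(50))
  k <- principal_curvatures(sph, c(0, 50 / sqrt(2), 50 / sqrt(2)))
  expect_equal(unname(k), c(1 / 50, 1 / 50), tolerance = 1e-6)
  expect_error(principal_curvatures(fit, c(0, 0, 0)), "centre")
})

test_that("surface ratio anisotropy is ~0 for concentric spheres and for similar ellipsoids", {
  ep <- make_voronoi_epithelium(hemi_spec(n_cells = 150))
  ly <- extract_layers(ep$volume)
  sel <- select_band(ep$volume, 30, ly)
  rec <- surface_ratio_anisotropy(ep$volume, ly, sel)
  expect_lte(rec$sra, 0.02)
  expect_equal(rec$SR_h, 45 / 33, tolerance = 0.05)  # concentric radii ratio
  expect_error(surface_ratio_anisotropy(ep$volume, ly, sel[1:5]), ">= 9")
})

test_that("sra follows the closed-form curvature oracle for sphere-over-oblate", {
  # apical sphere R = 60 over basal oblate (55, 55, 45): radii at selected
  # points from the analytic curvature formulas
  set.seed(2)
  n <- 40
  th <- runif(n, 0, 0.45 * pi); ph <- runif(n, 0, 2 * pi)
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  fit_a <- fit_ellipsoid(sphere_points(60))
  fit_b <- fit_ellipsoid(sphere_points(a = c(55, 55, 45)))
  ka <- t(apply(dirs * 60, 1, function(p) principal_curvatures(fit_a, p)))
  kb <- t(apply(dirs, 1, function(p) principal_curvatures(fit_b, p * c(55, 55, 45))))
  # analytic oracle for the oblate: curvature of (a, a, c) at polar angle
  oracle_k <- function(a, c_, dir) {
    # closed-form principal curvatures of the spheroid (a, a, c) at the
    # radial projection of `dir`: meridional 1/(a^2 c^2 w^3), azimuthal
    # 1/(a^2 w), with w = sqrt(u^2/a^4 + z^2/c^4)
    p <- dir * c(a, a, c_)   # same surface point as passed to the fit
    w <- sqrt((p[1]^2 + p[2]^2) / a^4 + p[3]^2 / c_^4)
    sort(c(1 / (a^2 * c_^2 * w^3), 1 / (a^2 * w)), decreasing = TRUE)
  }
  want <- t(apply(dirs, 1, function(d) oracle_k(55, 45, d)))
  expect_equal(unname(kb), unname(want), tolerance = 1e-6)
  R_a_h <- mean(1 / ka[, 1]); R_a_w <- mean(1 / ka[, 2])
  R_b_h <- mean(1 / kb[, 1]); R_b_w <- mean(1 / kb[, 2])
  sra_closed <- abs(R_a_h / R_b_h - R_a_w / R_b_w)
  expect_gt(sra_closed, 0)
  want_h <- mean(1 / want[, 1]); want_w <- mean(1 / want[, 2])
  sra_want <- abs(60 / want_h - 60 / want_w)
  expect_equal(sra_closed, sra_want, tolerance = 0.05)
})

test_that("sra is invariant under rigid rotation of the volume", {
  ep <- make_voronoi_epithelium(hemi_spec(n_cells = 150, rng_seed = 23))
  v <- ep$volume
  ly <- extract_layers(v)
  sel <- select_band(v, 30, ly)
  s1 <- surface_ratio_anisotropy(v, ly, sel)$sra
  # rotate 90 degrees about z: (y, x) -> (x, ny - y + 1)
  vox <- aperm(v$voxels, c(1, 3, 2))[, , dim(v$voxels)[2]:1]
  v2 <- label_volume(vox, v$spacing)
  ly2 <- extract_layers(v2)
  sel2 <- select_band(v2, 30, ly2)
  s2 <- surface_ratio_anisotropy(v2, ly2, sel2)$sra
  expect_lt(abs(s1 - s2), 0.02)
})

test_that("tissue surface ratio: flat slab 1, concentric caps R^2 scaling, monotone in thickness", {
  p <- make_prism_lattice(6, 6, cell_xy = 4, height = 8)
  expect_equal(tissue_surface_ratio(extract_layers(p)), 1, tolerance = 1e-3)
  # analytic concentric caps over the same solid angle, R_a = 2 R_b
  cap_layers <- function(Ra, Rb, half = pi / 3, sp = 0.5) {
    ext <- ceiling(Ra * sin(half) / sp) + 2
    n <- 2 * ext + 1
    ax <- ((1:n) - 0.5 - n / 2) * sp
    mk <- function(R) {
      r2 <- outer(ax^2, ax^2, "+")
      ins <- r2 <= (R * sin(half))^2
      dep <- matrix(NA_real_, n, n)
      dep[ins] <- 100 - sqrt(R^2 - r2[ins]) + 0.5   # depth in slice units (dz = 1)
      list(dep = dep, lab = ifelse(ins, 1L, 0L))
    }
    A <- mk(Ra); B <- mk(Rb)
    structure(list(apical_labels = A$lab, basal_labels = B$lab,
                   apical_depth = A$dep, basal_depth = B$dep,
                   spacing = c(1, sp, sp)), class = "layer_maps")
  }
  expect_equal(tissue_surface_ratio(cap_layers(60, 30)), 4, tolerance = 0.05 * 4)
  r1 <- tissue_surface_ratio(cap_layers(45, 30))
  r2 <- tissue_surface_ratio(cap_layers(36, 30))
  r3 <- tissue_surface_ratio(cap_layers(31, 30))
  expect_true(r1 > r2 && r2 > r3 && r3 > 1)
})

test_that("embryo axes report sphere and spheroid shape ratios", {
  vs <- solid_ellipsoid_volume(c(40, 40, 40))
  expect_equal(embryo_axes(vs)$aspect_ratio, 1, tolerance = 0.02)
  vo <- embryo_axes(solid_ellipsoid_volume(c(60, 60, 40)))
  expect_equal(vo$aspect_ratio, 1.5, tolerance = 0.02)
  expect_equal(vo$major_axes_ratio, 1, tolerance = 0.02)
  expect_equal(vo$lengths, c(120, 120, 80), tolerance = 0.02)
  vp <- embryo_axes(solid_ellipsoid_volume(c(60, 40, 40)))
  expect_equal(vp$major_axes_ratio, 1.5, tolerance = 0.02)
})
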