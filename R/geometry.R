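# Tissue-scale geometry: ellipsoid surface fits, principal curvatures,
# surface ratio anisotropy, tissue surface ratio and embryo axes.

#' Algebraic least-squares ellipsoid fit
#'
#' Fits a general (rotated) quadric to a point cloud by minimising the
#' algebraic residual of `x' Q x + b' x + c = 0` under a unit-norm
#' constraint (smallest right singular vector of the design matrix), then
#' rejects solutions that are not ellipsoids.
#'
#' @param points numeric matrix or data frame, n x 3 (columns x, y, z, um);
#'   at least 9 non-degenerate points.
#' @return Object of class `ellipsoid_fit`: `centre` (um), `semiaxes`
#'   (descending, um), `rotation` (3 x 3, columns are the axis directions
#'   matching `semiaxes`) and `residual` (RMS radial distance, um).
#' @export
fit_ellipsoid <- function(points) {
  p <- as.matrix(as.data.frame(points)[, 1:3])
  storage.mode(p) <- "double"
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < 9L) stop("ellipsoid fit needs >= 9 points")
  mu <- colMeans(p)
  q <- sweep(p, 2, mu)
  sc <- max(apply(q, 2, stats::sd))
  if (!is.finite(sc) || sc <= 0) stop("degenerate point set")
  q <- q / sc
  D <- cbind(q[, 1]^2, q[, 2]^2, q[, 3]^2,
             q[, 1] * q[, 2], q[, 1] * q[, 3], q[, 2] * q[, 3],
             q[, 1], q[, 2], q[, 3], 1)
  v <- svd(D, nu = 0)$v[, 10]
  Q <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                v[4] / 2, v[2], v[6] / 2,
                v[5] / 2, v[6] / 2, v[3]), 3, 3)
  b <- v[7:9]
  ctr <- tryCatch(solve(Q, -b / 2), error = function(e) stop("degenerate quadric"))
  k <- as.numeric(t(ctr) %*% Q %*% ctr) - v[10]
  e <- eigen(Q, symmetric = TRUE)
  if (any(e$values * k <= 0))
    stop("fitted quadric is not an ellipsoid")
  ax <- sqrt(k / e$values)
  ord <- order(ax, decreasing = TRUE)
  ax <- ax[ord]
  R <- e$vectors[, ord, drop = FALSE]
  centre <- ctr * sc + mu
  semiaxes <- ax * sc
  # RMS radial distance of points to the fitted surface
  u <- sweep(p, 2, centre) %*% R
  s <- sqrt((u[, 1] / semiaxes[1])^2 + (u[, 2] / semiaxes[2])^2 +
              (u[, 3] / semiaxes[3])^2)
  rad <- sqrt(rowSums(u^2))
  residual <- sqrt(mean((rad * abs(1 - 1 / pmax(s, .Machine$double.eps)) * s)^2))
  structure(list(centre = as.numeric(centre), semiaxes = as.numeric(semiaxes),
                 rotation = R, residual = residual),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf("<ellipsoid_fit> semi-axes %.2f x %.2f x %.2f um, residual %.3g um\n",
              x$semiaxes[1], x$semiaxes[2], x$semiaxes[3], x$residual))
  invisible(x)
}

#' Principal curvatures of a fitted ellipsoid at a point
#'
#' The point is first projected radially (along the ray from the fitted
#' centre) onto the surface; the two principal curvatures there are the
#' nonzero eigenvalues of the shape operator of the implicit surface.
#'
#' @param fit an [fit_ellipsoid()] result.
#' @param point numeric `c(x, y, z)` in um (not at the centre).
#' @return Named numeric `c(k_h, k_w)` in 1/um with `k_h >= k_w > 0`.
#' @export
principal_curvatures <- function(fit, point) {
  u <- as.numeric(t(fit$rotation) %*% (as.numeric(point) - fit$centre))
  s <- sqrt(sum((u / fit$semiaxes)^2))
  if (s < .Machine$double.eps) stop("point at the ellipsoid centre: curvature undefined")
  u <- u / s                       # radial projection onto the surface
  a2 <- fit$semiaxes^2
  grad <- 2 * u / a2
  ng <- sqrt(sum(grad^2))
  n <- grad / ng
  H <- diag(2 / a2)
  P <- diag(3) - tcrossprod(n)
  M <- (P %*% H %*% P) / ng
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(k_h = ev[1], k_w = ev[2])
}

#' Surface ratio anisotropy of the selected region
#'
#' Fits apical and basal ellipsoids to the respective surface pixel clouds,
#' evaluates the principal curvatures at every selected cell centroid
#' (projected to each surface), averages the radii of curvature `R = 1/k`
#' per surface and per axis class (h = greatest curvature, w = least), and
#' forms the two apical/basal surface ratios. Their absolute difference is
#' the surface ratio anisotropy: 0 for a tissue with isotropic curvature.
#'
#' @param volume a [label_volume()].
#' @param layers an [extract_layers()] result for the same volume.
#' @param selected integer vector of selected labels (>= 9 cells).
#' @param ratio_order `"average_then_ratio"` (default) or
#'   `"ratio_then_average"` (per-cell ratios averaged afterwards).
#' @return List of class `anisotropy_record`: mean radii `R_a_h, R_a_w,
#'   R_b_h, R_b_w` (um), ratios `SR_h, SR_w`, and `sra`.
#' @export
surface_ratio_anisotropy <- function(volume, layers, selected,
                                     ratio_order = c("average_then_ratio",
                                                     "ratio_then_average")) {
  ratio_order <- match.arg(ratio_order)
  if (length(selected) < 9L) stop("need >= 9 selected cells")
  fit_a <- fit_ellipsoid(surface_points(layers, "apical", trim_deepest = TRUE))
  fit_b <- fit_ellipsoid(surface_points(layers, "basal", trim_deepest = TRUE))
  cen <- cell_centroids(volume, selected)
  ka <- t(apply(cen[, c("x", "y", "z")], 1, function(p) principal_curvatures(fit_a, p)))
  kb <- t(apply(cen[, c("x", "y", "z")], 1, function(p) principal_curvatures(fit_b, p)))
  R_a_h <- mean(1 / ka[, 1]); R_a_w <- mean(1 / ka[, 2])
  R_b_h <- mean(1 / kb[, 1]); R_b_w <- mean(1 / kb[, 2])
  if (ratio_order == "average_then_ratio") {
    SR_h <- R_a_h / R_b_h
    SR_w <- R_a_w / R_b_w
  } else {
    SR_h <- mean(kb[, 1] / ka[, 1])
    SR_w <- mean(kb[, 2] / ka[, 2])
  }
  structure(list(R_a_h = R_a_h, R_a_w = R_a_w, R_b_h = R_b_h, R_b_w = R_b_w,
                 SR_h = SR_h, SR_w = SR_w, sra = abs(SR_h - SR_w),
                 fit_apical = fit_a, fit_basal = fit_b),
            class = "anisotropy_record")
}

#' @export
print.anisotropy_record <- function(x, ...) {
  cat(sprintf("<anisotropy_record> SR_h %.4f, SR_w %.4f, sra %.4f\n",
              x$SR_h, x$SR_w, x$sra))
  invisible(x)
}

surface_points <- function(layers, side = c("apical", "basal"),
                           trim_deepest = FALSE) {
  side <- match.arg(side)
  lab <- layers[[paste0(side, "_labels")]]
  dep <- layers[[paste0(side, "_depth")]]
  sp <- layers$spacing
  w <- which(lab > 0L, arr.ind = TRUE)
  d <- dep[w]
  if (trim_deepest && length(d)) {
    # drop the deepest slice: at the rim of an imaged cap the z-scan leaves
    # the segmented region through the lateral wall, not through the true
    # surface, producing a flat artifact sheet at the bottom of the stack
    keep <- d < max(d)
    if (any(keep)) { w <- w[keep, , drop = FALSE]; d <- d[keep] }
  }
  data.frame(x = (w[, 2] - 0.5) * sp[3], y = (w[, 1] - 0.5) * sp[2],
             z = (d - 0.5) * sp[1])
}

#' Tissue surface ratio (apical area / basal area)
#'
#' Each layer's depth map is treated as a heightfield over its footprint and
#' integrated as a triangulated surface; the ratio of apical to basal area
#' reflects the relative expansion of the apical surface (larger for thicker
#' curved shells, 1 for a flat slab).
#'
#' @param layers an [extract_layers()] result.
#' @param spacing optional spacing override `c(dz, dy, dx)` um.
#' @return Apical area divided by basal area.
#' @export
tissue_surface_ratio <- function(layers, spacing = layers$spacing) {
  a_ap <- heightfield_area(layers$apical_depth, layers$apical_labels > 0L, spacing)
  a_ba <- heightfield_area(layers$basal_depth, layers$basal_labels > 0L, spacing)
  if (a_ba <= 0) stop("empty basal surface")
  a_ap / a_ba
}

heightfield_area <- function(depth, mask, spacing) {
  z <- (depth - 0.5) * spacing[1]
  z[!mask] <- NA_real_
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2) stop("heightfield too small to triangulate")
  dy <- spacing[2]; dx <- spacing[3]
  z00 <- z[-nr, -nc]; z10 <- z[-1, -nc]; z01 <- z[-nr, -1]; z11 <- z[-1, -1]
  tri_area <- function(dza, dzb) {
    # triangle with legs along y (length dy, rise dza) and x (length dx, dzb)
    0.5 * sqrt((dy * dzb)^2 + (dx * dza)^2 + (dx * dy)^2)
  }
  a1 <- tri_area(z10 - z00, z01 - z00)   # (00, 10, 01)
  a2 <- tri_area(z01 - z11, z10 - z11)   # (11, 01, 10)
  sum(a1[!is.na(a1)]) + sum(a2[!is.na(a2)])
}

#' Embryo axis lengths and shape ratios
#'
#' Fits an ellipsoid to the outer surface of the (hole-filled) foreground
#' and reports the full axis lengths plus the aspect ratio (longest /
#' shortest, 1 for a sphere) and the major-axes ratio (longest /
#' second-longest, 1 for an oblate spheroid).
#'
#' @param volume a [label_volume()] with nonempty foreground.
#' @return List: `lengths` (descending, um), `aspect_ratio`,
#'   `major_axes_ratio`, and the underlying `fit`.
#' @export
embryo_axes <- function(volume) {
  v <- volume$voxels != 0L
  d <- dim(v)
  if (!any(v)) stop("empty foreground")
  filled <- v
  for (k in seq_len(d[1]))
    filled[k, , ] <- EBImage::fillHull(v[k, , ]) > 0
  # outer boundary: filled voxels with a 6-neighbour outside the filled set
  bnd <- filled & !(shift3(filled, 1, 1) & shift3(filled, 1, -1) &
                      shift3(filled, 2, 1) & shift3(filled, 2, -1) &
                      shift3(filled, 3, 1) & shift3(filled, 3, -1))
  w <- which(bnd, arr.ind = TRUE)
  sp <- volume$spacing
  pts <- data.frame(x = (w[, 3] - 0.5) * sp[3], y = (w[, 2] - 0.5) * sp[2],
                    z = (w[, 1] - 0.5) * sp[1])
  fit <- fit_ellipsoid(pts)
  lengths <- 2 * fit$semiaxes
  list(lengths = lengths,
       aspect_ratio = lengths[1] / lengths[3],
       major_axes_ratio = lengths[1] / lengths[2],
       fit = fit)
}

# shift a 3D logical array by +/-1 along axis, padding with FALSE
shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}
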