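# 3D convex hulls of voxelised cells.
#
# The convexity ratio needs the volume of the convex hull taken over the 8
# physical corners of every cell voxel (corners, not centres, so the hull
# always contains the voxel union and the ratio cannot exceed 1). The hull is
# computed with an in-package quickhull over a pruned corner set.

#' Volume of the 3D convex hull of a point set
#'
#' Quickhull with a relative plane-distance tolerance. Degenerate inputs
#' (fewer than 4 points, or all points coplanar) are an error.
#'
#' @param pts numeric matrix, n x 3 (columns x, y, z).
#' @param tol relative tolerance for on-plane classification.
#' @return Hull volume (same cubed units as `pts`).
#' @export
convex_hull_volume <- function(pts, tol = 1e-12) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs >= 4 distinct points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate point set")
  eps <- tol * scale

  # initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1])
  d1 <- colSums((t(pts) - pts[i1, ])^2)
  i2 <- which.max(d1)
  e1 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * e1[3] - rel[, 3] * e1[2],
              rel[, 3] * e1[1] - rel[, 1] * e1[3],
              rel[, 1] * e1[2] - rel[, 2] * e1[1])
  dline <- sqrt(rowSums(cr^2))
  i3 <- which.max(dline)
  if (dline[i3] <= eps * sqrt(sum(e1^2))) stop("degenerate (collinear) point set")
  nrm0 <- crossprod3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(rel %*% nrm0) / sqrt(sum(nrm0^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps) stop("degenerate (coplanar) point set")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, function(f) orient_face(f, pts, interior))
  # outside sets
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  outside <- assign_outside(faces, pts, remaining, eps)

  repeat {
    fi <- which(vapply(outside, length, 1L) > 0L)
    if (length(fi) == 0L) break
    fi <- fi[1]
    face <- faces[[fi]]
    cand <- outside[[fi]]
    dst <- plane_dist(face, pts, pts[cand, , drop = FALSE])
    p <- cand[which.max(dst)]
    vis <- which(vapply(faces, function(f) {
      plane_dist(f, pts, pts[p, , drop = FALSE]) > eps
    }, logical(1)))
    # horizon = edges used by exactly one visible face
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      v <- f$v
      rbind(sort(c(v[1], v[2])), sort(c(v[1], v[3])), sort(c(v[2], v[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    pool <- unique(unlist(outside[vis]))
    pool <- setdiff(pool, p)
    keep <- setdiff(seq_along(faces), vis)
    faces <- faces[keep]
    outside <- outside[keep]
    new_faces <- lapply(seq_len(nrow(horizon)), function(r) {
      orient_face(c(horizon[r, 1], horizon[r, 2], p), pts, interior)
    })
    new_outside <- assign_outside(new_faces, pts, pool, eps)
    faces <- c(faces, new_faces)
    outside <- c(outside, new_outside)
  }

  vol <- 0
  for (f in faces) {
    a <- pts[f$v[1], ] - interior
    b <- pts[f$v[2], ] - interior
    c3 <- pts[f$v[3], ] - interior
    vol <- vol + sum(a * crossprod3(b, c3))
  }
  # faces are oriented outward relative to `interior`, so each term is >= 0
  vol / 6
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orient_face <- function(v, pts, interior) {
  nrm <- crossprod3(pts[v[2], ] - pts[v[1], ], pts[v[3], ] - pts[v[1], ])
  if (sum(nrm * (interior - pts[v[1], ])) > 0) {
    v <- v[c(1, 3, 2)]
    nrm <- -nrm
  }
  list(v = v, n = nrm, nn = sqrt(sum(nrm^2)), d = sum(nrm * pts[v[1], ]))
}

plane_dist <- function(face, pts, q) {
  (q %*% face$n - face$d) / face$nn
}

assign_outside <- function(faces, pts, cand, eps) {
  out <- rep(list(integer(0)), length(faces))
  if (length(cand) == 0L) return(out)
  left <- cand
  for (k in seq_along(faces)) {
    if (length(left) == 0L) break
    dst <- plane_dist(faces[[k]], pts, pts[left, , drop = FALSE])
    sel <- dst > eps
    out[[k]] <- left[sel]
    left <- left[!sel]
  }
  out
}

# Candidate hull points for a voxelised cell: all distinct corner (x, y)
# lattice positions keep only their min and max corner z (interior corners of
# a z-run are convex combinations of the extremes and cannot be hull
# vertices).
#' @keywords internal
voxel_corner_points <- function(zyx, spacing) {
  # zyx: integer matrix of voxel indices (columns z, y, x), 1-based
  z0 <- rep(zyx[, 1], each = 2L) - rep(c(1L, 0L), nrow(zyx))
  corners <- expand.grid(dy = c(-1L, 0L), dx = c(-1L, 0L))
  acc_key <- integer(0); acc_z <- integer(0)
  ny1 <- max(zyx[, 2]) + 1L
  for (r in seq_len(nrow(corners))) {
    cy <- rep(zyx[, 2] + corners$dy[r], each = 2L)
    cx <- rep(zyx[, 3] + corners$dx[r], each = 2L)
    acc_key <- c(acc_key, cx * ny1 + cy)
    acc_z <- c(acc_z, z0)
  }
  o <- order(acc_key, acc_z)
  k <- acc_key[o]; zz <- acc_z[o]
  first <- !duplicated(k)
  last <- !duplicated(k, fromLast = TRUE)
  sel <- first | last
  k <- k[sel]; zz <- zz[sel]
  cx <- k %/% ny1; cy <- k %% ny1
  cbind(x = cx * spacing[3], y = cy * spacing[2], z = zz * spacing[1])
}
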