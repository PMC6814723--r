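# 3D computational geometry for small point sets (clones are 1-42 cells).
# Exhaustive-enumeration algorithms: a Delaunay tetrahedron is a 4-subset
# with a nonzero-volume circumsphere empty of all other points; a hull facet
# is a plane through 3 points with all points on one side. Cospherical ties
# (e.g. the corners of a cube) are resolved by a deterministic symbolic
# perturbation so results are unique and order-independent.

.coord_scale <- function(xyz) {
  s <- max(apply(xyz, 2L, function(v) diff(range(v))))
  if (s == 0) 1 else s
}

# Deterministic pseudo-random jitter keyed on point index and axis (no RNG
# state touched). Used only to break exact cosphericity/coplanarity ties.
.symbolic_jitter <- function(xyz, rel = 1e-6) {
  n <- nrow(xyz)
  h <- outer(seq_len(n), 1:3, function(i, a) {
    x <- sin(i * 12.9898 + a * 78.233) * 43758.5453
    x - floor(x)
  })
  xyz + (h - 0.5) * rel * .coord_scale(xyz)
}

.affine_rank <- function(xyz, tol = 1e-9) {
  if (nrow(xyz) < 2L) return(0L)
  cen <- sweep(xyz, 2L, colMeans(xyz))
  d <- svd(cen, nu = 0, nv = 0)$d
  sum(d > tol * max(d[1], .coord_scale(xyz)))
}

# Circumsphere of a nondegenerate tetrahedron: center c solves
# 2 (p_i - p_1) . c = |p_i|^2 - |p_1|^2, i = 2..4.
.circumsphere <- function(p) {
  A <- 2 * sweep(p[2:4, , drop = FALSE], 2L, p[1, ])
  b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
  center <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(center)) return(NULL)
  list(center = center, r2 = sum((p[1, ] - center)^2))
}

# All Delaunay tetrahedra (as 4-column index matrix) of >= 4 points in
# general position after symbolic perturbation.
.delaunay_tetrahedra <- function(xyz) {
  n <- nrow(xyz)
  P <- .symbolic_jitter(xyz)
  scale2 <- .coord_scale(P)^2
  combs <- combn(n, 4L)
  keep <- matrix(integer(0), ncol = 4L)
  for (j in seq_len(ncol(combs))) {
    id <- combs[, j]
    p <- P[id, , drop = FALSE]
    vol6 <- abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])))
    if (vol6 <= 1e-12 * scale2^1.5) next
    cs <- .circumsphere(p)
    if (is.null(cs)) next
    others <- P[-id, , drop = FALSE]
    if (nrow(others)) {
      d2 <- rowSums(sweep(others, 2L, cs$center)^2)
      if (any(d2 < cs$r2 - 1e-9 * scale2)) next
    }
    keep <- rbind(keep, id)
  }
  unname(keep)
}

#' Delaunay-triangulation edge lengths of a clone
#'
#' Measures clone dispersion as the lengths of all unique edges of the 3D
#' Delaunay triangulation of the member cell coordinates. Configurations
#' that do not admit a 3D triangulation -- fewer than 4 cells, or collinear
#' or coplanar point sets -- fall back to all pairwise distances, marked by
#' `fallback = TRUE`. Exact cosphericity ties are broken by a deterministic
#' symbolic perturbation (edge lengths are always measured on the original,
#' unperturbed coordinates).
#'
#' @param xyz numeric n x 3 coordinate matrix in micrometers (n >= 2).
#' @return List with `lengths` (sorted, micrometers), `fallback` (logical),
#'   and the summary statistics `mean`, `median`, `max`.
#' @export
delaunay_edge_lengths <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) {
    stop("dispersion undefined for singleton", call. = FALSE)
  }
  fallback <- nrow(xyz) < 4L || .affine_rank(xyz) < 3L
  if (!fallback) {
    tets <- .delaunay_tetrahedra(xyz)
    if (nrow(tets) == 0L) fallback <- TRUE
  }
  if (fallback) {
    lens <- as.numeric(dist(xyz))
  } else {
    pairs <- unique(do.call(rbind, apply(tets, 1L, function(t) {
      cbind(combn(sort(t), 2L)[1, ], combn(sort(t), 2L)[2, ])
    }, simplify = FALSE)))
    lens <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                            xyz[pairs[, 2], , drop = FALSE])^2))
  }
  lens <- sort(lens)
  list(lengths = lens, fallback = fallback,
       mean = mean(lens), median = median(lens), max = max(lens))
}

#' Convex-hull volume of a clone
#'
#' Volume of the 3D convex hull of the member cell coordinates, by
#' exhaustive supporting-plane enumeration: every facet plane is found as a
#' point triple with all points on one side, coplanar facet vertices are
#' ordered with a 2D convex hull in the facet plane, and the volume is
#' accumulated as pyramids from an interior point. Exact (to floating
#' point) for e.g. simplices and boxes. Fewer than 4 points, or affinely
#' dependent (collinear/coplanar) point sets, give volume 0 with
#' `degenerate = TRUE`.
#'
#' @param xyz numeric n x 3 coordinate matrix in micrometers.
#' @return List with `volume` (cubic micrometers) and `degenerate`.
#' @export
convex_hull_volume <- function(xyz) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 4L || .affine_rank(xyz) < 3L) {
    return(list(volume = 0, degenerate = TRUE))
  }
  scale <- .coord_scale(xyz)
  tol <- 1e-9 * scale
  O <- colMeans(xyz)
  combs <- combn(n, 3L)
  facets <- new.env(parent = emptyenv())
  for (j in seq_len(ncol(combs))) {
    id <- combs[, j]
    p1 <- xyz[id[1], ]; p2 <- xyz[id[2], ]; p3 <- xyz[id[3], ]
    u <- p2 - p1; v <- p3 - p1
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12 * scale^2) next # collinear triple
    nrm <- nrm / len
    s <- drop(xyz %*% nrm) - sum(nrm * p1)
    if (max(s) <= tol) {
      out_nrm <- nrm
    } else if (min(s) >= -tol) {
      out_nrm <- -nrm
    } else {
      next # not a supporting plane
    }
    members <- which(abs(s) <= tol)
    key <- paste(sort(members), collapse = ",")
    if (is.null(facets[[key]])) {
      facets[[key]] <- list(members = members, normal = out_nrm)
    }
  }
  vol <- 0
  for (key in ls(facets)) {
    f <- facets[[key]]
    pts <- xyz[f$members, , drop = FALSE]
    # orthonormal in-plane basis
    ref <- if (abs(f$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * f$normal) * f$normal
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(f$normal[2] * e1[3] - f$normal[3] * e1[2],
            f$normal[3] * e1[1] - f$normal[1] * e1[3],
            f$normal[1] * e1[2] - f$normal[2] * e1[1])
    uv <- cbind(drop(pts %*% e1), drop(pts %*% e2))
    ring <- grDevices::chull(uv)
    if (length(ring) < 3L) next
    poly <- pts[ring, , drop = FALSE]
    for (k in 2:(nrow(poly) - 1L)) {
      vol <- vol + abs(det(rbind(poly[1, ] - O, poly[k, ] - O,
                                 poly[k + 1L, ] - O))) / 6
    }
  }
  list(volume = vol, degenerate = FALSE)
}

#' Per-axis extents of a clone
#'
#' Maximum minus minimum member coordinate along each anatomical axis
#' (DV = y, ML = x, AP = z). A singleton clone has zero extent on all axes.
#'
#' @param xyz numeric n x 3 coordinate matrix in micrometers
#'   (columns x, y, z).
#' @return Named numeric vector `extent_dv`, `extent_ml`, `extent_ap`
#'   (micrometers).
#' @export
axis_extents <- function(xyz) {
  xyz <- as.matrix(xyz)
  r <- unname(apply(xyz, 2L, function(v) diff(range(v))))
  c(extent_dv = r[2], extent_ml = r[1], extent_ap = r[3])
}
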