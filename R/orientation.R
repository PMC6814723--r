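#' Fit a clone's principal axis
#'
#' The main axis of a clone is the line `L(t) = M + t V` where `M` is the
#' mean of the member cell coordinates and `V` the direction of largest
#' variance, obtained by singular value decomposition of the centered
#' coordinates (equivalently, the top eigenvector of the coordinate
#' variance-covariance matrix). The axis is unsigned; `V` is canonicalized
#' to a non-negative DV (y) component, breaking exact zeros by requiring
#' the first nonzero component positive. A (near-)tie between the top two
#' singular values means the principal direction is not unique and is
#' flagged (`degenerate`), with the deterministic SVD result retained.
#'
#' @param xyz numeric n x 3 coordinate matrix in micrometers (n >= 2, not
#'   all points identical).
#' @param radial unit vector of the radial (cortical depth) direction,
#'   default the DV axis `c(0, 1, 0)`.
#' @return Object of class `principal_axis`: `M`, `V` (unit),
#'   `singular_values` (descending), `angle_to_radial` (degrees, [0, 90]),
#'   `length_um` (extent of member projections onto `V`),
#'   `radial_projection_um`, `degenerate`.
#' @export
fit_principal_axis <- function(xyz, radial = c(0, 1, 0)) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop("axis undefined", call. = FALSE)
  cen <- sweep(xyz, 2L, colMeans(xyz))
  s <- svd(cen, nu = 0)
  if (s$d[1] <= 1e-12 * max(1, .coord_scale(xyz))) {
    stop("axis undefined", call. = FALSE) # all points identical
  }
  V <- s$v[, 1]
  # canonical sign: non-negative DV component, lexicographic tie-break
  if (V[2] < 0 || (V[2] == 0 && (V[1] < 0 || (V[1] == 0 && V[3] < 0)))) {
    V <- -V
  }
  proj <- drop(cen %*% V)
  len <- diff(range(proj))
  ang <- radial_angle(V, radial)
  structure(list(
    M = colMeans(xyz), V = V, singular_values = s$d,
    angle_to_radial = ang, length_um = len,
    radial_projection_um = abs(sum(V * radial)) * len,
    degenerate = s$d[2] > (1 - 1e-6) * s$d[1]
  ), class = "principal_axis")
}

#' Folded angle between an unsigned axis and the radial direction
#'
#' Because a principal axis has no sign, the angle is folded to [0, 90]
#' degrees: `acos(|V . radial|)`.
#'
#' @param V unit 3-vector (axis direction).
#' @param radial unit 3-vector (default DV axis).
#' @return Angle in degrees in [0, 90].
#' @export
radial_angle <- function(V, radial = c(0, 1, 0)) {
  nv <- sqrt(sum(V^2)); nr <- sqrt(sum(radial^2))
  if (nv == 0 || nr == 0) stop("zero vector", call. = FALSE)
  acos(pmin(1, abs(sum(V * radial)) / (nv * nr))) * 180 / pi
}

#' Uniform random rotation matrices on SO(3)
#'
#' Haar-uniform rotations via uniform unit quaternions (Shoemake's method):
#' with u1, u2, u3 ~ U(0,1), the quaternion
#' `(sqrt(1-u1) sin 2*pi*u2, sqrt(1-u1) cos 2*pi*u2,
#'   sqrt(u1) sin 2*pi*u3,  sqrt(u1) cos 2*pi*u3)`
#' is uniform on the 3-sphere. Uses the current RNG stream.
#'
#' @param n number of rotations.
#' @return Array `3 x 3 x n` of rotation matrices.
#' @export
random_rotations <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  qx <- sqrt(1 - u1) * sin(2 * pi * u2)
  qy <- sqrt(1 - u1) * cos(2 * pi * u2)
  qz <- sqrt(u1) * sin(2 * pi * u3)
  qw <- sqrt(u1) * cos(2 * pi * u3)
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- 1 - 2 * (qy^2 + qz^2)
  R[1, 2, ] <- 2 * (qx * qy - qz * qw)
  R[1, 3, ] <- 2 * (qx * qz + qy * qw)
  R[2, 1, ] <- 2 * (qx * qy + qz * qw)
  R[2, 2, ] <- 1 - 2 * (qx^2 + qz^2)
  R[2, 3, ] <- 2 * (qy * qz - qx * qw)
  R[3, 1, ] <- 2 * (qx * qz - qy * qw)
  R[3, 2, ] <- 2 * (qy * qz + qx * qw)
  R[3, 3, ] <- 1 - 2 * (qx^2 + qy^2)
  R
}

# rotate unit vectors (rows of vmat, recycled) by rotations in R (3x3xn)
.rotate_rows <- function(vmat, R) {
  n <- dim(R)[3]
  out <- matrix(0, n, 3)
  for (j in 1:3) {
    out[, j] <- R[j, 1, ] * vmat[, 1] + R[j, 2, ] * vmat[, 2] +
      R[j, 3, ] * vmat[, 3]
  }
  out
}

#' Randomized-rotation null for clone axis orientation
#'
#' Builds the null distribution of radial angles expected if clone axes had
#' no preferred orientation: each observed axis is randomly rotated in 3D
#' (uniformly on SO(3), so the rotated axes are equally spaced on the
#' sphere) and the folded angle to the radial direction recorded. Under
#' this null the angle has density sin(theta) on [0, 90] degrees
#' (median 60 degrees, E[cos theta] = 1/2). The empirical p-value is the
#' fraction of null replicate means (mean angle over clones per rotation
#' draw) at or below the observed mean angle, i.e. a test for radial
#' (smaller-than-chance) orientation.
#'
#' @param axes a single `principal_axis`, a list of them, or a k x 3 matrix
#'   of unit axis vectors.
#' @param n_rotations number of random rotations per axis (default 1000).
#' @param seed integer seed (the null is reproducible given the seed).
#' @param radial radial unit vector (default DV axis).
#' @return Object of class `rotation_null`: `null_angles` (all k *
#'   n_rotations folded angles, degrees), `null_means` (per-draw means),
#'   `observed_angles`, `observed_mean`, `p_value`, `summary`
#'   (mean/median/quantiles of the null), `n_rotations`, `seed`.
#' @export
rotation_null <- function(axes, n_rotations = 1000, seed = 1,
                          radial = c(0, 1, 0)) {
  if (n_rotations < 1) stop("n_rotations must be >= 1", call. = FALSE)
  if (inherits(axes, "principal_axis")) axes <- list(axes)
  vmat <- if (is.list(axes)) {
    do.call(rbind, lapply(axes, function(a) a$V))
  } else {
    as.matrix(axes)
  }
  stopifnot(ncol(vmat) == 3)
  k <- nrow(vmat)
  observed <- apply(vmat, 1L, radial_angle, radial = radial)
  null_angles <- matrix(NA_real_, n_rotations, k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (i in seq_len(k)) {
    R <- random_rotations(n_rotations)
    rot <- .rotate_rows(vmat[rep(i, n_rotations), , drop = FALSE], R)
    cosang <- abs(rot %*% radial) / sqrt(rowSums(rot^2))
    null_angles[, i] <- acos(pmin(1, cosang)) * 180 / pi
  }
  null_means <- rowMeans(null_angles)
  obs_mean <- mean(observed)
  structure(list(
    null_angles = as.numeric(null_angles),
    null_means = null_means,
    observed_angles = observed,
    observed_mean = obs_mean,
    p_value = mean(null_means <= obs_mean),
    summary = c(mean = mean(null_angles),
                median = median(null_angles),
                quantile(null_angles, c(0.05, 0.25, 0.75, 0.95))),
    n_rotations = n_rotations, seed = seed
  ), class = "rotation_null")
}

#' @export
print.rotation_null <- function(x, ...) {
  cat(sprintf("<rotation_null> %d axes x %d rotations (seed %d)\n",
              length(x$observed_angles), x$n_rotations, x$seed))
  cat(sprintf("  observed mean angle %.1f deg; null mean %.1f deg; p = %.4g\n",
              x$observed_mean, mean(x$null_means), x$p_value))
  invisible(x)
}
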