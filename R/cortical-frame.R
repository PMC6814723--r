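#' Cortical frame: pial and ventricular boundary polylines
#'
#' Depth within the cortex is normalized between the manually drawn upper
#' (pial) and lower (ventricular) boundary masks of a section. Boundaries
#' are piecewise-linear polylines in the section plane with `x` = ML
#' position and `y` = DV position (y increases from pia toward ventricle);
#' they must be single-valued in `x` over the region of interest.
#'
#' @param pial,ventricular numeric n x 2 matrices (columns x, y in
#'   micrometers) or data frames with columns `x`, `y`.
#' @param section_id optional identifier linking the frame to a serial
#'   section.
#' @return Object of class `cortical_frame`.
#' @export
cortical_frame <- function(pial, ventricular, section_id = NULL) {
  as_poly <- function(p, what) {
    p <- as.matrix(as.data.frame(p))
    if (ncol(p) < 2L || nrow(p) < 2L || !all(is.finite(p[, 1:2]))) {
      stop("invalid ", what, " polyline: need >= 2 finite (x, y) points",
           call. = FALSE)
    }
    p <- p[order(p[, 1]), 1:2, drop = FALSE]
    colnames(p) <- c("x", "y")
    p
  }
  f <- structure(list(pial = as_poly(pial, "pial"),
                      ventricular = as_poly(ventricular, "ventricular"),
                      section_id = section_id),
                 class = "cortical_frame")
  xs <- range(c(f$pial[, 1], f$ventricular[, 1]))
  probe <- seq(xs[1], xs[2], length.out = 25)
  if (any(.boundary_y(f$ventricular, probe) <= .boundary_y(f$pial, probe))) {
    stop("ventricular boundary must lie below (larger y than) the pial boundary",
         call. = FALSE)
  }
  f
}

# y of a polyline at ML positions x, by linear interpolation between
# vertices (clamped to the nearest segment beyond the polyline ends).
.boundary_y <- function(poly, x) {
  approx(poly[, 1], poly[, 2], xout = x, rule = 2, ties = mean)$y
}

#' Local cortical thickness
#'
#' @param frame a [cortical_frame()].
#' @param x_um ML position(s) in micrometers.
#' @return Thickness in micrometers (ventricular y minus pial y).
#' @export
cortical_thickness <- function(frame, x_um) {
  .boundary_y(frame$ventricular, x_um) - .boundary_y(frame$pial, x_um)
}

#' Relative cortical depth of cells
#'
#' Normalized DV position: `d_pial / (d_pial + d_vent)` where the two
#' distances are measured along the DV axis from the cell to each boundary
#' at the cell's ML position (0 at the pia, 1 at the ventricular limit).
#' Cells outside the band `[-tol, 1 + tol]` are an error; small
#' out-of-band excursions within the tolerance are clamped to [0, 1].
#'
#' @param x_um,y_um cell coordinates in micrometers (vectorized).
#' @param frame a [cortical_frame()].
#' @param tol out-of-band tolerance as a fraction of thickness
#'   (default 0.02).
#' @param cell_id optional ids used in error messages.
#' @return Numeric vector of depths in [0, 1].
#' @export
relative_depth <- function(x_um, y_um, frame, tol = 0.02, cell_id = NULL) {
  yp <- .boundary_y(frame$pial, x_um)
  yv <- .boundary_y(frame$ventricular, x_um)
  th <- yv - yp
  if (any(th <= 0)) stop("non-positive cortical thickness", call. = FALSE)
  depth <- (y_um - yp) / th
  bad <- depth < -tol | depth > 1 + tol
  if (any(bad)) {
    who <- if (!is.null(cell_id)) cell_id[bad] else which(bad)
    stop("cell(s) outside the cortical band: ",
         paste(head(who, 5), collapse = ", "), call. = FALSE)
  }
  pmin(pmax(depth, 0), 1)
}

#' Clone depth summary: barycenter, upper/lower class and depth bins
#'
#' The clone barycenter is the arithmetic mean of the member cells'
#' relative DV positions; clones with barycenter above mid-depth are
#' classed upper (`"U"`), otherwise lower (`"L"`). Cells are also assigned
#' to `n_bins` equal depth bins (bin 1 = pial surface; a depth of exactly 1
#' is clamped into the last bin).
#'
#' @param depths relative depths of the member cells (from
#'   [relative_depth()]).
#' @param n_bins number of equal depth bins (default 6).
#' @return List with `barycenter_depth`, `upper_lower` (`"U"`/`"L"`), and
#'   `bin_index` (integer vector, 1-based).
#' @export
clone_depth_summary <- function(depths, n_bins = 6) {
  stopifnot(length(depths) >= 1L, all(is.finite(depths)), n_bins >= 1)
  bary <- mean(depths)
  bins <- pmin(floor(depths * n_bins), n_bins - 1L) + 1L
  list(barycenter_depth = bary,
       upper_lower = if (bary < 0.5) "U" else "L",
       bin_index = as.integer(bins))
}

#' Relative clonal dispersion per cell
#'
#' Clone spread along an axis expressed as % of the local cortical
#' thickness, divided by the clone size: `(extent / thickness * 100) / n`.
#' The thickness is evaluated at the clone barycenter's ML position.
#' Singleton clones have zero dispersion.
#'
#' @param xyz numeric n x 3 member coordinate matrix (micrometers).
#' @param frame a [cortical_frame()].
#' @param axis `"DV"` or `"ML"`.
#' @return Percent of cortical thickness per cell.
#' @export
relative_dispersion <- function(xyz, frame, axis = c("DV", "ML")) {
  axis <- match.arg(axis)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) return(0)
  th <- cortical_thickness(frame, mean(xyz[, 1]))
  if (th <= 0) stop("non-positive cortical thickness", call. = FALSE)
  ext <- unname(axis_extents(xyz)[if (axis == "DV") "extent_dv" else "extent_ml"])
  (ext / th * 100) / nrow(xyz)
}

#' Read cortical frames from JSON
#'
#' One record per serial section:
#' `{"section_id": ..., "pial": [[x, y], ...], "ventricular": [[x, y], ...]}`
#' (micrometers), or a single such object.
#'
#' @param path JSON file.
#' @return A single [cortical_frame()] if the file holds one record, else a
#'   list of frames named by `section_id`.
#' @export
read_frame_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  build <- function(rec) {
    cortical_frame(rec$pial, rec$ventricular, section_id = rec$section_id)
  }
  if (!is.null(raw$pial)) return(build(raw))
  frames <- lapply(seq_len(length(raw)), function(i) build(raw[[i]]))
  names(frames) <- vapply(frames, function(f) as.character(f$section_id %||% ""),
                          character(1))
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a
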