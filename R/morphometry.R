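#' Read a reconstructed arbor from an SWC file
#'
#' Standard SWC: 7 whitespace-separated columns
#' (`id type x y z radius parent`), `#` comments, one root with parent -1.
#' Coordinates can be rescaled (e.g. to restore physical micrometers from
#' voxel-indexed reconstructions) with anisotropic factors. Nodes are
#' returned in a normalized parent-before-child order.
#'
#' @param path SWC file.
#' @param scale numeric length-3 scaling `(sx, sy, sz)` applied to the
#'   coordinates (default no scaling).
#' @return Data frame of class `swc_arbor` with columns `id`, `type`, `x`,
#'   `y`, `z`, `radius`, `parent`.
#' @export
read_swc <- function(path, scale = c(1, 1, 1)) {
  stopifnot(length(scale) == 3, all(is.finite(scale)), all(scale > 0))
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  validate_arbor(within(tab, {
    x <- x * scale[1]; y <- y * scale[2]; z <- z * scale[3]
  }))
}

#' @rdname read_swc
#' @param arbor candidate arbor node table.
#' @export
validate_arbor <- function(arbor) {
  if (anyDuplicated(arbor$id)) {
    stop("duplicated node id(s): ",
         paste(head(arbor$id[duplicated(arbor$id)], 3), collapse = ", "),
         call. = FALSE)
  }
  roots <- arbor$id[arbor$parent == -1]
  if (length(roots) != 1L) {
    stop("arbor must have exactly one root (parent -1), found ",
         length(roots), call. = FALSE)
  }
  dangling <- !(arbor$parent %in% c(-1, arbor$id))
  if (any(dangling)) {
    stop("node(s) with absent parent id: node ",
         paste(head(arbor$id[dangling], 3), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(arbor$radius) | arbor$radius <= 0)) {
    stop("non-positive radius at node ",
         paste(head(arbor$id[!is.finite(arbor$radius) | arbor$radius <= 0], 3),
               collapse = ", "), call. = FALSE)
  }
  # topological order (also proves acyclicity)
  order_ids <- roots
  placed <- setNames(logical(nrow(arbor)), arbor$id)
  placed[as.character(roots)] <- TRUE
  remaining <- arbor$id[arbor$parent != -1]
  parent_of <- setNames(arbor$parent, arbor$id)
  while (length(remaining)) {
    ready <- remaining[placed[as.character(parent_of[as.character(remaining)])]]
    if (!length(ready)) {
      stop("cycle or disconnected subtree involving node(s): ",
           paste(head(remaining, 3), collapse = ", "), call. = FALSE)
    }
    placed[as.character(ready)] <- TRUE
    order_ids <- c(order_ids, ready)
    remaining <- setdiff(remaining, ready)
  }
  out <- arbor[match(order_ids, arbor$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("swc_arbor", "data.frame")
  out
}

#' Write an arbor back to SWC
#'
#' @param arbor an `swc_arbor`.
#' @param path output file.
#' @export
write_swc <- function(arbor, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  write.table(as.data.frame(arbor)[, c("id", "type", "x", "y", "z",
                                       "radius", "parent")],
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arbor morphometrics
#'
#' Extracts the standard single-cell metrics from a reconstructed arbor:
#' \describe{
#'   \item{branches}{maximal paths between consecutive topological events
#'     (root/soma exit, branch point, tip); a node with `k >= 2` children
#'     is a single branch point spawning `k` branches (trifurcations are
#'     flagged).}
#'   \item{total_length}{sum of inter-node segment lengths (micrometers).}
#'   \item{model_volume}{sum of truncated-cone (frustum) volumes
#'     `pi h / 3 (r1^2 + r1 r2 + r2^2)` over segments (cubic micrometers).}
#'   \item{endings}{tip count.}
#'   \item{densities}{branch and ending counts per unit of a territory
#'     proxy: the convex-hull volume of all node positions. The proxy can
#'     be overridden by an externally measured territorial volume.}
#' }
#' Soma nodes (structure code 1) are excluded from branch topology and
#' from length/volume (soma-to-soma segments are cell body, not arbor),
#' but their positions count toward the territory hull.
#'
#' @param arbor an `swc_arbor` from [read_swc()] / [validate_arbor()].
#' @param territory_volume_um3 optional externally measured territorial
#'   volume (cubic micrometers) overriding the convex-hull proxy.
#' @return List of class `arbor_metrics`: `n_branches`, `total_length`,
#'   `model_volume`, `n_endings`, `n_bifurcations`, `multifurcation_flag`,
#'   `territory_volume_proxy`, `territory_is_proxy`, `branch_density`,
#'   `ending_density`, `degenerate` (single-node arbor).
#' @export
arbor_metrics <- function(arbor, territory_volume_um3 = NULL) {
  stopifnot(inherits(arbor, "swc_arbor"))
  n <- nrow(arbor)
  idx_of <- setNames(seq_len(n), arbor$id)
  is_soma <- arbor$type == 1
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- arbor$parent[i]
    if (p != -1) {
      pi_ <- idx_of[[as.character(p)]]
      children[[pi_]] <- c(children[[pi_]], i)
    }
  }
  # arbor children = non-soma children (soma-soma edges are cell body)
  arbor_children <- lapply(children, function(ch) ch[!is_soma[ch]])
  n_children <- lengths(arbor_children)
  # events: origins are soma nodes with arbor children, or a non-soma root
  root_idx <- which(arbor$parent == -1)
  origin <- is_soma & n_children > 0
  if (!is_soma[root_idx]) origin[root_idx] <- TRUE
  branch_pt <- !is_soma & n_children >= 2
  tip <- !is_soma & n_children == 0
  seg_len <- function(a, b) {
    sqrt(sum((unlist(arbor[a, c("x", "y", "z")]) -
                unlist(arbor[b, c("x", "y", "z")]))^2))
  }
  frustum <- function(a, b) {
    h <- seg_len(a, b); r1 <- arbor$radius[a]; r2 <- arbor$radius[b]
    pi * h / 3 * (r1^2 + r1 * r2 + r2^2)
  }
  n_branches <- 0L
  total_length <- 0
  model_volume <- 0
  starts <- unlist(lapply(which(origin | branch_pt), function(i) {
    arbor_children[[i]]
  }))
  for (s in starts) {
    n_branches <- n_branches + 1L
    prev <- idx_of[[as.character(arbor$parent[s])]]
    cur <- s
    repeat {
      total_length <- total_length + seg_len(prev, cur)
      model_volume <- model_volume + frustum(prev, cur)
      if (branch_pt[cur] || tip[cur]) break
      nxt <- arbor_children[[cur]]
      if (length(nxt) == 0L) break
      prev <- cur
      cur <- nxt[1]
    }
  }
  hull <- convex_hull_volume(as.matrix(arbor[, c("x", "y", "z")]))
  territory <- territory_volume_um3 %||% hull$volume
  degenerate <- n < 2L
  dens_ok <- !degenerate && territory > 0
  structure(list(
    n_branches = n_branches,
    total_length = total_length,
    model_volume = model_volume,
    n_endings = max(sum(tip), 1L),
    n_bifurcations = sum(branch_pt),
    multifurcation_flag = any(n_children >= 3),
    territory_volume_proxy = territory,
    territory_is_proxy = is.null(territory_volume_um3),
    branch_density = if (dens_ok) n_branches / territory else NA_real_,
    ending_density = if (dens_ok) sum(tip) / territory else NA_real_,
    degenerate = degenerate
  ), class = "arbor_metrics")
}

#' @export
print.arbor_metrics <- function(x, ...) {
  cat(sprintf(paste0("<arbor_metrics> %d branches, %d endings, %d branch",
                     " points\n  total length %.1f um, model volume %.1f um^3,",
                     " territory %s %.3g um^3\n"),
              x$n_branches, x$n_endings, x$n_bifurcations, x$total_length,
              x$model_volume, if (x$territory_is_proxy) "(hull proxy)" else "",
              x$territory_volume_proxy))
  invisible(x)
}
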