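# Connected components of the graph joining point pairs whose Euclidean
# distance satisfies `cmp` against `threshold`. Returns integer membership,
# deterministically renumbered by first occurrence in `order_key` order.
.distance_components <- function(xyz, threshold, strict = TRUE,
                                 order_key = seq_len(nrow(xyz))) {
  n <- nrow(xyz)
  if (n == 1L) return(1L)
  d <- as.matrix(dist(xyz))
  adj <- if (strict) d < threshold else d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  # renumber components by the smallest order_key they contain
  first <- vapply(split(order_key, memb), min, order_key[1])
  as.integer(match(memb, names(sort(first))))
}

#' Call clones from rare displays and spatial linkage
#'
#' Partitions cells into clones: within each (animal, stage, rare display)
#' group, cells are joined whenever their 3D distance is strictly below the
#' linkage threshold, and each connected component of this graph (single
#' linkage) is one clone. A clone therefore never spans animals, stages or
#' displays. The linkage criterion is "sister cells less than `linkage_um`
#' apart"; because single linkage can chain, a component whose maximum
#' pairwise distance reaches or exceeds `linkage_um` is still emitted but
#' flagged (`diameter_flag`). Cells whose display is not rare remain
#' unassigned (`clone_id` is `NA`).
#'
#' @param cells validated cell table, coordinates in micrometers.
#' @param rare rare display set: a character vector of display keys
#'   (applied to every animal) or a per-animal data frame with columns
#'   `animal_id`, `display` (as returned by [select_rare_displays()]).
#' @param linkage_um spatial linkage threshold in micrometers (default 600,
#'   strict `<`).
#' @return A list of class `clone_set`:
#'   \describe{
#'     \item{cells}{input table with added `clone_id` (`NA` if unassigned).}
#'     \item{clones}{one row per clone: `clone_id`, `animal_id`, `stage`,
#'       `display`, `n_cells`, `max_pairwise_um`, `diameter_flag`.}
#'   }
#' @export
call_clones <- function(cells, rare, linkage_um = 600) {
  cells <- validate_cells(cells)
  stopifnot(linkage_um > 0)
  rare_for_animal <- function(animal) {
    if (is.data.frame(rare)) rare$display[rare$animal_id == animal] else rare
  }
  # order-invariance: process in a canonical order
  ord <- order(cells$animal_id, cells$stage, cells$display, cells$cell_id)
  cells_o <- cells[ord, , drop = FALSE]
  key <- interaction(cells_o$animal_id, cells_o$stage, cells_o$display,
                     drop = TRUE, lex.order = TRUE)
  cells_o$clone_id <- NA_character_
  clone_rows <- list()
  for (grp in levels(key)) {
    idx <- which(key == grp)
    animal <- cells_o$animal_id[idx[1]]
    disp <- cells_o$display[idx[1]]
    if (!disp %in% rare_for_animal(animal)) next
    xyz <- as.matrix(cells_o[idx, c("x_um", "y_um", "z_um")])
    memb <- .distance_components(xyz, linkage_um, strict = TRUE,
                                 order_key = cells_o$cell_id[idx])
    for (k in sort(unique(memb))) {
      sel <- idx[memb == k]
      cid <- sprintf("%s|%s|%s|%02d", animal, cells_o$stage[sel[1]], disp, k)
      cells_o$clone_id[sel] <- cid
      dmax <- if (length(sel) > 1L) {
        max(dist(as.matrix(cells_o[sel, c("x_um", "y_um", "z_um")])))
      } else 0
      clone_rows[[cid]] <- data.frame(
        clone_id = cid, animal_id = animal, stage = cells_o$stage[sel[1]],
        display = disp, n_cells = length(sel), max_pairwise_um = dmax,
        diameter_flag = dmax >= linkage_um, stringsAsFactors = FALSE
      )
    }
  }
  cells_out <- cells_o[order(match(cells_o$cell_id, cells$cell_id)), ,
                       drop = FALSE]
  rownames(cells_out) <- NULL
  clones <- if (length(clone_rows)) {
    out <- do.call(rbind, clone_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(clone_id = character(0), animal_id = character(0),
               stage = character(0), display = character(0),
               n_cells = integer(0), max_pairwise_um = numeric(0),
               diameter_flag = logical(0), stringsAsFactors = FALSE)
  }
  structure(list(cells = cells_out, clones = clones,
                 linkage_um = linkage_um),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("<clone_set> %d clones from %d cells (%d assigned), linkage < %g um\n",
              nrow(x$clones), nrow(x$cells), sum(!is.na(x$cells$clone_id)),
              x$linkage_um))
  if (nrow(x$clones)) {
    cat(sprintf("  clone sizes: %s (median %g)\n",
                paste(range(x$clones$n_cells), collapse = "-"),
                median(x$clones$n_cells)))
  }
  invisible(x)
}

#' Coordinates of one clone's member cells
#'
#' @param clone_set result of [call_clones()].
#' @param clone_id a clone identifier present in `clone_set$clones`.
#' @return Numeric matrix (n x 3) of member coordinates in micrometers,
#'   columns `x_um`, `y_um`, `z_um`; rownames are cell ids.
#' @export
clone_coords <- function(clone_set, clone_id) {
  sel <- !is.na(clone_set$cells$clone_id) &
    clone_set$cells$clone_id == clone_id
  if (!any(sel)) stop("unknown clone_id: ", clone_id, call. = FALSE)
  m <- as.matrix(clone_set$cells[sel, c("x_um", "y_um", "z_um")])
  rownames(m) <- clone_set$cells$cell_id[sel]
  m
}
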