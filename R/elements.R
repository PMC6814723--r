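#' Decompose a clone into connected elements
#'
#' Sister cells separated by more than the disconnection distance (the
#' stage-specific astrocyte mean diameter + s.d.) are considered
#' disconnected. Elements are the connected components of the graph joining
#' cell pairs at distance less than or equal to `disconnect_um`; an element
#' of two or more cells is a *cluster* of apposed cells, a singleton
#' element is an *isolated cell*.
#'
#' @param xyz numeric n x 3 coordinate matrix in micrometers; rownames (if
#'   any) are used as cell ids.
#' @param disconnect_um disconnection threshold in micrometers
#'   (connectivity is `<=`, i.e. disconnection is strictly "greater than").
#' @return List with `elements` (list of cell-id/index vectors),
#'   `n_elements`, and `clustered_cells` (number of cells in elements of
#'   size >= 2; a singleton clone has `clustered_cells = 0`).
#' @export
decompose_elements <- function(xyz, disconnect_um) {
  stopifnot(disconnect_um > 0)
  xyz <- as.matrix(xyz)
  ids <- if (!is.null(rownames(xyz))) rownames(xyz) else seq_len(nrow(xyz))
  memb <- .distance_components(xyz, disconnect_um, strict = FALSE,
                               order_key = ids)
  elements <- split(ids, memb)
  names(elements) <- NULL
  sizes <- lengths(elements)
  list(elements = elements, n_elements = length(elements),
       clustered_cells = sum(sizes[sizes >= 2L]))
}

#' Detect sister-cell doublets
#'
#' Sister cells whose somata lie closer than the mean astrocyte nuclear
#' size (6 micrometers, strict `<`) form doublets. Components of exactly
#' two cells under this proximity graph are doublets; larger components are
#' reported separately as multiplets (their cells do not count as doublet
#' cells).
#'
#' @param xyz numeric n x 3 coordinate matrix in micrometers; rownames (if
#'   any) are used as cell ids.
#' @param doublet_um proximity threshold in micrometers (default 6).
#' @return List with `doublets` (list of id pairs), `multiplets` (list of
#'   id vectors of size >= 3), and `n_doublet_cells`.
#' @export
detect_doublets <- function(xyz, doublet_um = 6) {
  stopifnot(doublet_um > 0)
  xyz <- as.matrix(xyz)
  ids <- if (!is.null(rownames(xyz))) rownames(xyz) else seq_len(nrow(xyz))
  memb <- .distance_components(xyz, doublet_um, strict = TRUE,
                               order_key = ids)
  comps <- split(ids, memb)
  sizes <- lengths(comps)
  list(doublets = unname(comps[sizes == 2L]),
       multiplets = unname(comps[sizes >= 3L]),
       n_doublet_cells = 2L * sum(sizes == 2L))
}

#' Within-clone pair distances among marker-positive cells
#'
#' For birth-dating analyses: within each clone, the 3D distances among
#' cells positive for a marker (e.g. EdU). Clones with exactly two positive
#' cells contribute one pair; clones with more contribute all pairwise
#' distances, flagged as multiway.
#'
#' @param clone_set result of [call_clones()].
#' @param filter name of a logical column of the cell table (e.g. `"edu"`),
#'   or a logical vector aligned with `clone_set$cells`.
#' @return Data frame with columns `clone_id`, `cell_a`, `cell_b`,
#'   `distance_um`, `multiway`.
#' @export
pair_distances <- function(clone_set, filter = "edu") {
  cells <- clone_set$cells
  pos <- if (is.character(filter)) isTRUE_vec(cells[[filter]]) else isTRUE_vec(filter)
  cells <- cells[pos & !is.na(cells$clone_id), , drop = FALSE]
  out <- list()
  for (cid in unique(cells$clone_id)) {
    sub <- cells[cells$clone_id == cid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    pr <- combn(nrow(sub), 2L)
    d <- sqrt(colSums((t(sub[pr[1, ], c("x_um", "y_um", "z_um")]) -
                         t(sub[pr[2, ], c("x_um", "y_um", "z_um")]))^2))
    out[[cid]] <- data.frame(
      clone_id = cid, cell_a = sub$cell_id[pr[1, ]],
      cell_b = sub$cell_id[pr[2, ]], distance_um = as.numeric(d),
      multiway = nrow(sub) > 2L, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(clone_id = character(0), cell_a = character(0),
                      cell_b = character(0), distance_um = numeric(0),
                      multiway = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# NA-safe logical coercion (NA counts as negative)
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
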