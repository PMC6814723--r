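#' Assemble and validate a labeled-cell table
#'
#' The cell table is the central input: one row per labeled cell with 3D
#' coordinates in micrometers and the per-compartment color display. The
#' coordinate convention is `x` = mediolateral (ML), `y` = dorsoventral
#' depth (DV, increasing from the pial surface toward the ventricle),
#' `z` = anteroposterior (AP).
#'
#' @param cell_id unique cell identifiers.
#' @param animal_id,stage animal and developmental stage annotations
#'   (non-empty strings, e.g. `"P7"`).
#' @param x_um,y_um,z_um coordinates in micrometers (finite).
#' @param cyto,nuc per-compartment FP sets in any notation accepted by
#'   [fp_set()].
#' @param subtype optional astrocyte morphotype, one of `"PrA"`, `"PiA"`,
#'   `"intermediate"`, `"unknown"`.
#' @param edu,ki67 optional logical marker flags.
#' @return A `data.frame` with canonical columns `cell_id`, `animal_id`,
#'   `stage`, `x_um`, `y_um`, `z_um`, `cyto_display`, `nuc_display`,
#'   `display`, `subtype`, `edu`, `ki67`.
#' @export
cell_table <- function(cell_id, animal_id, stage, x_um, y_um, z_um,
                       cyto, nuc, subtype = "unknown",
                       edu = NA, ki67 = NA) {
  n <- length(cell_id)
  df <- data.frame(
    cell_id = as.character(cell_id),
    animal_id = rep_len(as.character(animal_id), n),
    stage = rep_len(as.character(stage), n),
    x_um = as.numeric(x_um), y_um = as.numeric(y_um), z_um = as.numeric(z_um),
    cyto_display = vapply(rep_len(as.character(cyto), n), fp_set, character(1)),
    nuc_display = vapply(rep_len(as.character(nuc), n), fp_set, character(1)),
    subtype = rep_len(as.character(subtype), n),
    edu = rep_len(as.logical(edu), n),
    ki67 = rep_len(as.logical(ki67), n),
    stringsAsFactors = FALSE
  )
  df$display <- paste0(df$cyto_display, "/", df$nuc_display)
  validate_cells(df)
}

#' @rdname cell_table
#' @param cells a candidate cell table.
#' @export
validate_cells <- function(cells) {
  req <- c("cell_id", "animal_id", "stage", "x_um", "y_um", "z_um", "display")
  miss <- setdiff(req, names(cells))
  if (length(miss)) {
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicated cell_id: ",
         paste(head(unique(cells$cell_id[duplicated(cells$cell_id)]), 3),
               collapse = ", "), call. = FALSE)
  }
  for (ax in c("x_um", "y_um", "z_um")) {
    bad <- !is.finite(cells[[ax]])
    if (any(bad)) {
      stop("non-finite ", ax, " coordinate for cell_id: ",
           paste(head(cells$cell_id[bad], 3), collapse = ", "), call. = FALSE)
    }
  }
  if (any(!nzchar(cells$animal_id)) || any(!nzchar(cells$stage))) {
    stop("animal_id and stage must be non-empty", call. = FALSE)
  }
  unl <- !display_is_labeled(cells$display)
  if (any(unl)) {
    stop("fully default (unlabeled) cells are not admissible: cell_id ",
         paste(head(cells$cell_id[unl], 3), collapse = ", "), call. = FALSE)
  }
  rownames(cells) <- NULL
  cells
}

#' Read a labeled-cell table from CSV/TSV
#'
#' Required columns: `cell_id`, `animal_id`, `stage`, `x_um`, `y_um`,
#' `cyto_display`, `nuc_display` (semicolon-joined subsets of `C;Y;R`,
#' empty allowed), plus either `z_um` or `z` with `z_unit` in
#' `{um, section}`. Section-indexed `z` is converted to micrometers as
#' `z_um = z * section_thickness_um` (serial-section datasets store the
#' section number as the AP coordinate). Optional columns `subtype`,
#' `edu`, `ki67` are carried through.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param section_thickness_um section thickness used to convert
#'   section-indexed `z`; default 80 (micrometers).
#' @return Validated cell table (see [cell_table()]); attribute
#'   `z_is_section` records whether `z` was section-indexed.
#' @export
read_cells <- function(path, section_thickness_um = 80) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character")
  for (col in c("x_um", "y_um", "z_um", "z")) {
    if (col %in% names(raw)) raw[[col]] <- as.numeric(raw[[col]])
  }
  z_is_section <- FALSE
  if (!"z_um" %in% names(raw)) {
    if (!"z" %in% names(raw)) stop("need column z_um, or z with z_unit")
    unit <- if ("z_unit" %in% names(raw)) raw$z_unit else "um"
    if (any(!unit %in% c("um", "section"))) {
      stop("z_unit must be 'um' or 'section'")
    }
    if (length(unique(unit)) > 1L) {
      stop("mixed z units in one table are not supported")
    }
    z_is_section <- unit[1] == "section"
    raw$z_um <- if (z_is_section) raw$z * section_thickness_um else raw$z
  }
  opt <- function(col, default) if (col %in% names(raw)) raw[[col]] else default
  cells <- cell_table(
    cell_id = raw$cell_id, animal_id = raw$animal_id, stage = raw$stage,
    x_um = raw$x_um, y_um = raw$y_um, z_um = raw$z_um,
    cyto = opt("cyto_display", ""), nuc = opt("nuc_display", ""),
    subtype = opt("subtype", "unknown"),
    edu = as.logical(opt("edu", NA)), ki67 = as.logical(opt("ki67", NA))
  )
  attr(cells, "z_is_section") <- z_is_section
  cells
}
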