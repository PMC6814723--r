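#' @name color-display
#' @title Combinatorial color displays
#'
#' @description
#' A *color display* is the observable label of one cell: the set of
#' fluorescent proteins (FPs) detected in its cytoplasm and the set detected
#' in its nucleus, each a subset of the three Brainbow FPs cyan (`"C"`),
#' yellow (`"Y"`) and red (`"R"`). Displays are the clonal identity key:
#' sister cells inherit the recombination outcome of their progenitor and
#' therefore share one display.
#'
#' Displays are encoded as canonical character keys `"<cyto>/<nuc>"` where
#' each side lists its FPs in the fixed order C, Y, R (e.g. `"CY/R"`;
#' an unlabeled compartment is empty, e.g. `"/R"`). The fully default state
#' `"/"` is *unlabeled* and never a valid display for a labeled cell.
NULL

# Fixed FP order used by every canonical encoding.
.FP <- c("C", "Y", "R")

#' Canonicalize one compartment's FP set
#'
#' Accepts `"C;Y"`, `"YC"`, `c("Y","C")`, `""` or `NA` and returns the
#' canonical compact string (`"CY"`, `""`).
#'
#' @param x FP set in any of the accepted notations.
#' @return Canonical compact string.
#' @export
fp_set <- function(x) {
  if (length(x) == 1L && (is.na(x) || x == "")) return("")
  parts <- if (length(x) > 1L) x else strsplit(gsub("[;, ]+", "", x), "")[[1]]
  parts <- unique(parts)
  bad <- setdiff(parts, .FP)
  if (length(bad)) {
    stop("unknown fluorescent protein code(s): ", paste(bad, collapse = ", "),
         " (expected subset of C, Y, R)", call. = FALSE)
  }
  paste(.FP[.FP %in% parts], collapse = "")
}

#' Canonical display key from compartment sets
#'
#' @param cyto,nuc cytoplasmic and nuclear FP sets, each in any notation
#'   accepted by [fp_set()]. Vectorized (equal length or length 1 recycling).
#' @return Character vector of canonical keys `"<cyto>/<nuc>"`.
#' @examples
#' display_key("Y;C", "R")  # "CY/R"
#' display_key("", "R")     # "/R"
#' @export
display_key <- function(cyto, nuc) {
  n <- max(length(cyto), length(nuc))
  cyto <- rep_len(as.character(cyto), n)
  nuc <- rep_len(as.character(nuc), n)
  paste0(vapply(cyto, fp_set, character(1)), "/",
         vapply(nuc, fp_set, character(1)))
}

#' Split a canonical display key into its compartment sets
#'
#' @param key character vector of canonical keys.
#' @return Data frame with columns `cyto` and `nuc` (compact strings).
#' @export
parse_display <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)
  data.frame(
    cyto = vapply(parts, function(p) if (length(p) >= 1) p[1] else "", character(1)),
    nuc = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)),
    stringsAsFactors = FALSE
  )
}

#' Is a display labeled / co-labeled?
#'
#' `display_is_labeled()`: at least one compartment carries an FP.
#' `display_is_colabeled()`: both compartments carry at least one FP, i.e.
#' the cell coexpresses at least one copy of each transgene -- the first
#' criterion for a display to be usable as a clonal mark.
#'
#' @param key character vector of canonical display keys.
#' @return Logical vector.
#' @export
display_is_labeled <- function(key) {
  p <- parse_display(key)
  nchar(p$cyto) > 0L | nchar(p$nuc) > 0L
}

#' @rdname display_is_labeled
#' @export
display_is_colabeled <- function(key) {
  p <- parse_display(key)
  nchar(p$cyto) > 0L & nchar(p$nuc) > 0L
}

# All FP subsets reachable in one compartment when the cell carries between
# 1 and max_copies copies of the compartment's transgene, each copy
# independently staying default or expressing exactly one FP. Reached by
# literal enumeration of per-copy outcome assignments.
.reachable_sets <- function(max_copies) {
  if (max_copies < 1L) return("")
  outcomes <- c("", .FP) # default or one FP per copy
  sets <- character(0)
  for (k in seq_len(max_copies)) {
    grid <- do.call(expand.grid,
                    c(rep(list(outcomes), k), stringsAsFactors = FALSE))
    sets <- c(sets, apply(grid, 1L, function(row) {
      fp_set(paste(row[row != ""], collapse = ";"))
    }))
  }
  unique(sets)
}

#' Enumerate theoretical color combinations
#'
#' Counts every distinguishable color display of a cell carrying between 1
#' and `max_copies_per_transgene` genomic copies of each of the two
#' transgenes (cytoplasmic and nuclear), where each copy independently
#' either remains default or expresses exactly one of the three FPs in its
#' compartment. Distinguishability is at the level of per-compartment FP
#' sets; the fully default state (no FP in either compartment) is excluded.
#' With up to three copies of each transgene this yields 63 combinations.
#'
#' @param max_copies_per_transgene integer >= 0; 0 means no copies and hence
#'   no labeled state.
#' @return List with `count` (integer) and `states`, a data frame with
#'   columns `cyto`, `nuc`, `display` (canonical key), ordered
#'   lexicographically on the key.
#' @examples
#' enumerate_theoretical_combinations(3)$count # 63
#' @export
enumerate_theoretical_combinations <- function(max_copies_per_transgene) {
  stopifnot(length(max_copies_per_transgene) == 1L,
            !is.na(max_copies_per_transgene),
            max_copies_per_transgene >= 0)
  m <- as.integer(max_copies_per_transgene)
  sets <- .reachable_sets(m)
  states <- expand.grid(cyto = sets, nuc = sets, stringsAsFactors = FALSE)
  states$display <- paste0(states$cyto, "/", states$nuc)
  states <- states[states$display != "/", , drop = FALSE]
  states <- states[order(states$display), , drop = FALSE]
  rownames(states) <- NULL
  list(count = nrow(states), states = states)
}
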