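#' Tabulate color-display frequencies
#'
#' Inventories the distinct color displays of a labeled-cell table and their
#' frequencies, either pooled over all animals (the default, matching a
#' pooled multi-animal inventory) or per animal.
#'
#' @param cells validated cell table (see [cell_table()]).
#' @param scope `"pooled"` or `"per_animal"`.
#' @return Data frame with columns `animal_id` (only for per-animal scope),
#'   `display`, `cyto`, `nuc`, `n`, `fraction`, ordered lexicographically on
#'   the display key within each scope; attribute `total_cells` gives the
#'   total count (per scope for per-animal tables, as a named vector).
#' @export
tabulate_display_frequencies <- function(cells, scope = c("pooled", "per_animal")) {
  scope <- match.arg(scope)
  if (is.null(cells) || nrow(cells) == 0L) stop("no labeled cells", call. = FALSE)
  cells <- validate_cells(cells)
  tab_one <- function(keys) {
    counts <- table(keys)
    df <- data.frame(display = names(counts), n = as.integer(counts),
                     stringsAsFactors = FALSE)
    df$fraction <- df$n / sum(df$n)
    df <- df[order(df$display), , drop = FALSE]
    cbind(df["display"], parse_display(df$display), df[c("n", "fraction")])
  }
  if (scope == "pooled") {
    out <- tab_one(cells$display)
    attr(out, "total_cells") <- nrow(cells)
  } else {
    pieces <- lapply(split(cells$display, cells$animal_id), tab_one)
    out <- do.call(rbind, Map(function(a, df) cbind(animal_id = a, df),
                              names(pieces), pieces))
    rownames(out) <- NULL
    attr(out, "total_cells") <-
      vapply(split(cells$display, cells$animal_id), length, integer(1))
  }
  attr(out, "scope") <- scope
  out
}

#' Select rare co-labeled displays
#'
#' A display qualifies as a clonal mark when (i) both compartments carry at
#' least one FP (coexpression of at least one copy of each transgene) and
#' (ii) its frequency among labeled cells is strictly below the rarity
#' threshold (default 2%).
#'
#' @param freq frequency table from [tabulate_display_frequencies()].
#' @param threshold rarity cut as a fraction in (0, 1]; strict `<`.
#' @return For pooled tables, a character vector of display keys. For
#'   per-animal tables, a data frame with columns `animal_id`, `display`
#'   (a display may be rare in one animal and common in another).
#' @export
select_rare_displays <- function(freq, threshold = 0.02) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- freq$fraction < threshold & display_is_colabeled(freq$display)
  if (identical(attr(freq, "scope"), "per_animal")) {
    out <- freq[keep, c("animal_id", "display"), drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    freq$display[keep]
  }
}
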