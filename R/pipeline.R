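#' Pipeline configuration
#'
#' All analysis thresholds in one place. `disconnect_um` is the
#' stage-specific disconnection distance (astrocyte mean diameter + s.d.;
#' not printed in reference datasets, so these are implementation defaults
#' to be overridden with measured values when available).
#'
#' @param rarity_threshold rarity cut for clonal displays (fraction,
#'   strict `<`; default 0.02).
#' @param rarity_scope `"pooled"` (default) or `"per_animal"`.
#' @param linkage_um clone spatial-linkage threshold (micrometers).
#' @param disconnect_um named per-stage disconnection distances
#'   (micrometers); unnamed stages fall back to `disconnect_default_um`.
#' @param disconnect_default_um fallback disconnection distance.
#' @param doublet_um doublet distance (micrometers, strict `<`).
#' @param n_bins number of cortical depth bins.
#' @param depth_tol out-of-band tolerance for relative depth.
#' @param n_rotations rotation-null draws.
#' @param seed seed for the rotation null.
#' @param section_thickness_um section thickness for section-indexed z.
#' @param dunn_adjust multiplicity adjustment family for Dunn post hoc
#'   (any method of [stats::p.adjust()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(rarity_threshold = 0.02,
                            rarity_scope = c("pooled", "per_animal"),
                            linkage_um = 600,
                            disconnect_um = c(P7 = 60, P21 = 70),
                            disconnect_default_um = 60,
                            doublet_um = 6,
                            n_bins = 6,
                            depth_tol = 0.02,
                            n_rotations = 1000,
                            seed = 1,
                            section_thickness_um = 80,
                            dunn_adjust = "bonferroni") {
  structure(list(rarity_threshold = rarity_threshold,
                 rarity_scope = match.arg(rarity_scope),
                 linkage_um = linkage_um, disconnect_um = disconnect_um,
                 disconnect_default_um = disconnect_default_um,
                 doublet_um = doublet_um, n_bins = n_bins,
                 depth_tol = depth_tol, n_rotations = n_rotations,
                 seed = as.integer(seed),
                 section_thickness_um = section_thickness_um,
                 dunn_adjust = dunn_adjust),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys missing from the file keep their [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  known <- names(cfg)
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- if (k == "disconnect_um") unlist(user[[k]]) else user[[k]]
  cfg
}

.disconnect_for_stage <- function(config, stage) {
  d <- config$disconnect_um
  if (!is.null(names(d)) && stage %in% names(d)) unname(d[[stage]])
  else config$disconnect_default_um
}

#' Composition class of a clone from member subtypes
#'
#' @param subtypes character vector of member subtypes.
#' @return `"PrA-only"`, `"PiA-only"`, `"heterogeneous"`, or `"unknown"`
#'   (no member with a known morphotype).
#' @export
clone_composition <- function(subtypes) {
  has_pra <- any(subtypes %in% c("PrA", "intermediate"))
  has_pia <- any(subtypes == "PiA")
  if (has_pra && has_pia) "heterogeneous"
  else if (has_pia) "PiA-only"
  else if (has_pra) "PrA-only"
  else "unknown"
}

#' Full spatial summary of one clone
#'
#' Computes every clone-level spatial statistic: per-axis extents,
#' Delaunay edge-length summaries, convex-hull volume, decomposition into
#' elements, doublets, principal-axis orientation, and (when a cortical
#' frame is supplied) depth-derived quantities.
#'
#' @param xyz n x 3 member coordinate matrix (micrometers); rownames are
#'   cell ids.
#' @param frame optional [cortical_frame()].
#' @param disconnect_um disconnection distance (micrometers).
#' @param doublet_um doublet distance (micrometers).
#' @param n_bins depth bins.
#' @param depth_tol depth tolerance.
#' @return One-row data frame of summary statistics.
#' @export
clone_spatial_summary <- function(xyz, frame = NULL, disconnect_um = 60,
                                  doublet_um = 6, n_bins = 6,
                                  depth_tol = 0.02) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  ext <- axis_extents(xyz)
  del <- if (n >= 2) delaunay_edge_lengths(xyz) else NULL
  hull <- convex_hull_volume(xyz)
  elems <- decompose_elements(xyz, disconnect_um)
  dbl <- detect_doublets(xyz, doublet_um)
  ax <- if (n >= 2 && max(dist(xyz)) > 0) fit_principal_axis(xyz) else NULL
  out <- data.frame(
    n_cells = n,
    extent_dv = ext[["extent_dv"]], extent_ml = ext[["extent_ml"]],
    extent_ap = ext[["extent_ap"]],
    delaunay_mean = if (!is.null(del)) del$mean else NA_real_,
    delaunay_median = if (!is.null(del)) del$median else NA_real_,
    delaunay_max = if (!is.null(del)) del$max else NA_real_,
    delaunay_fallback = if (!is.null(del)) del$fallback else NA,
    hull_volume_um3 = hull$volume, hull_degenerate = hull$degenerate,
    n_elements = elems$n_elements, clustered_cells = elems$clustered_cells,
    n_doublet_cells = dbl$n_doublet_cells,
    n_doublets = length(dbl$doublets),
    axis_angle_deg = if (!is.null(ax)) ax$angle_to_radial else NA_real_,
    axis_degenerate = if (!is.null(ax)) ax$degenerate else NA,
    radial_projection_um = if (!is.null(ax)) ax$radial_projection_um else NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(frame)) {
    depths <- relative_depth(xyz[, 1], xyz[, 2], frame, tol = depth_tol,
                             cell_id = rownames(xyz))
    ds <- clone_depth_summary(depths, n_bins)
    out$barycenter_depth <- ds$barycenter_depth
    out$upper_lower <- ds$upper_lower
    out$relative_dispersion_dv <- relative_dispersion(xyz, frame, "DV")
    out$relative_dispersion_ml <- relative_dispersion(xyz, frame, "ML")
  }
  out
}

#' Run the full clonal-analysis pipeline
#'
#' Orchestrates the whole analysis on a cell table: display frequency
#' inventory, rare-display selection, clone calling, per-clone spatial
#' summaries (plus depth statistics when a cortical frame is given and
#' orientation statistics when z has true 3D resolution), per-stage
#' aggregates and nonparametric group comparisons.
#'
#' @param cells validated cell table, or a path readable by [read_cells()].
#' @param frame optional [cortical_frame()] (or path to a frame JSON).
#' @param config a [pipeline_config()].
#' @param orientation `"auto"` (skip when z is section-indexed), `TRUE` or
#'   `FALSE`.
#' @param quiet suppress progress messages.
#' @return List of class `run_report`: `clone_table` (one row per clone
#'   with all statistics), `aggregates` (per stage), `tests`,
#'   `rotation_null`, `frequencies`, `rare_displays`, `clone_set`,
#'   `provenance`.
#' @export
run_pipeline <- function(cells, frame = NULL, config = pipeline_config(),
                         orientation = "auto", quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(cells)) {
    cells <- read_cells(cells, config$section_thickness_um)
  }
  if (is.character(frame)) frame <- read_frame_json(frame)
  z_is_section <- isTRUE(attr(cells, "z_is_section"))
  cells <- validate_cells(cells)
  say("ingest: %d labeled cells, %d animal(s), stage(s) %s",
      nrow(cells), length(unique(cells$animal_id)),
      paste(unique(cells$stage), collapse = "/"))

  freq <- tabulate_display_frequencies(cells, scope = config$rarity_scope)
  rare <- select_rare_displays(freq, threshold = config$rarity_threshold)
  n_rare <- if (is.data.frame(rare)) nrow(rare) else length(rare)
  say("inventory: %d distinct displays, %d rare co-labeled (< %g%%)",
      length(unique(freq$display)), n_rare, 100 * config$rarity_threshold)
  if (n_rare == 0L) warning("empty rare display set: no clones can be called")

  clone_set <- call_clones(cells, rare, linkage_um = config$linkage_um)
  say("clone calling: %d clones from %d assigned cells",
      nrow(clone_set$clones), sum(!is.na(clone_set$cells$clone_id)))

  clone_table <- clone_set$clones
  if (nrow(clone_table)) {
    summaries <- lapply(seq_len(nrow(clone_table)), function(i) {
      cid <- clone_table$clone_id[i]
      xyz <- clone_coords(clone_set, cid)
      tryCatch(
        clone_spatial_summary(
          xyz, frame = frame,
          disconnect_um = .disconnect_for_stage(config, clone_table$stage[i]),
          doublet_um = config$doublet_um, n_bins = config$n_bins,
          depth_tol = config$depth_tol),
        error = function(e) {
          stop("spatial summary failed for clone ", cid, ": ",
               conditionMessage(e), call. = FALSE)
        })
    })
    comp <- vapply(clone_table$clone_id, function(cid) {
      clone_composition(
        clone_set$cells$subtype[!is.na(clone_set$cells$clone_id) &
                                  clone_set$cells$clone_id == cid])
    }, character(1))
    clone_table <- cbind(clone_table,
                         composition_class = unname(comp),
                         do.call(rbind, summaries))
    rownames(clone_table) <- NULL
  }

  do_orient <- if (identical(orientation, "auto")) !z_is_section
               else isTRUE(orientation)
  rot_null <- NULL
  if (do_orient && nrow(clone_table)) {
    ok <- which(clone_table$n_cells >= 2 & !is.na(clone_table$axis_angle_deg))
    if (length(ok)) {
      axes <- lapply(clone_table$clone_id[ok], function(cid) {
        fit_principal_axis(clone_coords(clone_set, cid))
      })
      rot_null <- rotation_null(axes, n_rotations = config$n_rotations,
                                seed = config$seed)
      say("orientation: mean angle %.1f deg vs null %.1f deg (p = %.3g)",
          rot_null$observed_mean, mean(rot_null$null_means),
          rot_null$p_value)
    }
  } else if (!do_orient) {
    say("orientation: skipped (section-scale z resolution)")
  }

  aggregates <- .aggregate_by_stage(clone_table)
  tests <- .standard_tests(clone_table, config)

  provenance <- list(
    config_hash = .obj_md5(config),
    input_hash = .obj_md5(cells),
    seed = config$seed,
    n_cells = nrow(cells), n_rare_displays = n_rare,
    n_clones = nrow(clone_table),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(clone_table = clone_table, aggregates = aggregates,
                 tests = tests, rotation_null = rot_null,
                 frequencies = freq, rare_displays = rare,
                 clone_set = clone_set, config = config,
                 provenance = provenance),
            class = "run_report")
}

.obj_md5 <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

.aggregate_by_stage <- function(clone_table) {
  if (!nrow(clone_table)) {
    return(data.frame(stage = character(0)))
  }
  pieces <- lapply(split(clone_table, clone_table$stage), function(ct) {
    data.frame(
      stage = ct$stage[1],
      n_clones = nrow(ct),
      mean_size = mean(ct$n_cells), sem_size = .sem(ct$n_cells),
      mean_n_elements = mean(ct$n_elements),
      sem_n_elements = .sem(ct$n_elements),
      clustered_pct = 100 * sum(ct$clustered_cells) / sum(ct$n_cells),
      doublet_pct = 100 * sum(ct$n_doublet_cells) / sum(ct$n_cells),
      pra_only_pct = 100 * mean(ct$composition_class == "PrA-only"),
      pia_only_pct = 100 * mean(ct$composition_class == "PiA-only"),
      heterogeneous_pct = 100 * mean(ct$composition_class == "heterogeneous"),
      mean_hull_volume_um3 = mean(ct$hull_volume_um3),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.standard_tests <- function(clone_table, config) {
  tests <- list()
  if (!nrow(clone_table)) return(tests)
  stages <- unique(clone_table$stage)
  if (length(stages) >= 2) {
    groups <- split(clone_table$n_cells, clone_table$stage)
    tests$size_by_stage <- compare_groups(groups, adjust = config$dunn_adjust)
  }
  if ("upper_lower" %in% names(clone_table)) {
    u <- clone_table$n_cells[clone_table$upper_lower == "U"]
    l <- clone_table$n_cells[clone_table$upper_lower == "L"]
    if (length(u) >= 1 && length(l) >= 1) {
      tests$size_upper_vs_lower <- compare_groups(list(U = u, L = l))
    }
  }
  tests
}

#' Nonparametric group comparison
#'
#' Two groups: Mann-Whitney (Wilcoxon rank-sum) test, exact p when sample
#' sizes permit, two-sided unless stated otherwise. Three or more groups:
#' Kruskal-Wallis test with Dunn's multiple-comparison post hoc
#' (multiplicity-adjusted).
#'
#' @param ... numeric vectors (one per group), or a single (optionally
#'   named) list of numeric vectors.
#' @param alternative alternative hypothesis for the two-group test.
#' @param adjust p-adjustment family for the Dunn post hoc.
#' @return List with `method`, `statistic`, `p_value`, `groups` (sizes),
#'   and for >= 3 groups a `posthoc` data frame.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value # exact 0.1
#' @export
compare_groups <- function(..., alternative = "two.sided",
                           adjust = "bonferroni") {
  args <- list(...)
  groups <- if (length(args) == 1L && is.list(args[[1]]) &&
                  !is.data.frame(args[[1]])) args[[1]] else args
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  stopifnot(all(vapply(groups, is.numeric, logical(1))),
            all(lengths(groups) >= 1))
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across groups; p = 1")
    return(list(method = "degenerate (all ties)", statistic = NA_real_,
                p_value = 1, groups = lengths(groups)))
  }
  if (length(groups) == 2L) {
    wt <- suppressWarnings(
      wilcox.test(groups[[1]], groups[[2]], alternative = alternative))
    list(method = paste0("Mann-Whitney (", alternative, ")"),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         groups = lengths(groups))
  } else {
    kw <- kruskal.test(groups)
    list(method = "Kruskal-Wallis + Dunn",
         statistic = unname(kw$statistic), p_value = kw$p.value,
         groups = lengths(groups),
         posthoc = dunn_posthoc(groups, adjust = adjust))
  }
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise z statistics on the pooled Kruskal-Wallis rank means with the
#' tie correction, adjusted for multiplicity.
#'
#' @param groups named list of numeric vectors.
#' @param adjust any [stats::p.adjust()] method (default `"bonferroni"`).
#' @return Data frame with columns `group_a`, `group_b`, `z`, `p_unadj`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = "bonferroni") {
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(names(groups), 2L)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  p_unadj <- 2 * pnorm(-abs(z))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
             p_unadj = p_unadj,
             p_adj = pmin(1, p.adjust(p_unadj, method = adjust)),
             stringsAsFactors = FALSE)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d clones, %d cells assigned of %d\n",
              nrow(x$clone_table),
              sum(!is.na(x$clone_set$cells$clone_id)),
              nrow(x$clone_set$cells)))
  if (nrow(x$aggregates)) {
    print(x$aggregates, digits = 3)
  }
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %s: %s p = %.3g\n", nm, t$method, t$p_value))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `clones.csv` (per-clone table), `aggregates.csv`, `tests.json`,
#' and `provenance.json`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$clone_table, file.path(dir, "clones.csv"),
            row.names = FALSE)
  write.csv(report$aggregates, file.path(dir, "aggregates.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$tests, file.path(dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", force = TRUE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
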