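#' Configuration for the synthetic labeled-cortex generator
#'
#' Defaults emulate the statistical structure of a multicolor-labeled P7
#' cortical volume: overdispersed clone sizes (negative binomial, mean 7.1,
#' s.d. 4.6, observed range 1-42), clones decomposed into 1 + Poisson(1.8)
#' spatially separated elements, ~20% of cells in sub-6-um doublets,
#' clone subtype composition 76/5/19% (protoplasmic-only / pial-only /
#' heterogeneous), larger clones in the upper half of the cortex, and a
#' display-frequency spectrum with both common and rare combinatorial
#' labels.
#'
#' @param seed integer RNG seed.
#' @param n_clones number of ground-truth clones.
#' @param n_animals clones are spread evenly across this many animals.
#' @param stage developmental stage annotation (default `"P7"`).
#' @param slab_um labeled volume per animal, micrometers
#'   `(dv_thickness, ml_width, ap_depth)`.
#' @param copy_number_probs probabilities of carrying 1, 2 or 3 genomic
#'   copies of each transgene (default uniform).
#' @param recomb_probs per-copy recombination outcome probabilities
#'   `(C, Y, R, default)`.
#' @param clone_size_mean,clone_size_sd,clone_size_max negative-binomial
#'   clone-size law (overall mean, s.d.) truncated to
#'   `[1, clone_size_max]`.
#' @param elements_rate clone element count is `1 + Poisson(elements_rate)`
#'   truncated at the clone size.
#' @param element_spread_um Gaussian s.d. of cell scatter within an element
#'   (apposed somata; must be well below the disconnection threshold).
#' @param element_spacing_um typical spacing between element centers.
#' @param doublet_fraction target fraction of cells belonging to doublets.
#' @param doublet_um doublet distance (partner placed strictly below this).
#' @param subtype_mix clone composition probabilities
#'   `(PrA, PiA, heterogeneous)`.
#' @param pia_depth relative depth band occupied by pial astrocytes
#'   (PiA cells lie at depth < `pia_depth`).
#' @param upper_size_multiplier multiplicative size factor for clones
#'   whose center lies in the upper half of the cortex (the base mean is
#'   rescaled so `clone_size_mean` stays the overall expectation).
#' @param background_fraction fraction of all labeled cells that are
#'   non-clonal background bearing common displays (default 0.85; real
#'   multicolor inventories are dominated by common displays, with
#'   rare-display clonal cells a small minority).
#' @param unique_rare_displays if `TRUE` (default) each clone receives a
#'   display unique within its animal, drawn from the co-labeled display
#'   states excluding the common background displays; if `FALSE`, clone
#'   displays are sampled from the stochastic label-genotype model and may
#'   collide.
#' @return Validated list of class `generation_config`.
#' @export
generation_config <- function(seed = 1,
                              n_clones = 200,
                              n_animals = 5,
                              stage = "P7",
                              slab_um = c(dv = 1400, ml = 2000, ap = 2000),
                              copy_number_probs = c(`1` = 1, `2` = 1, `3` = 1) / 3,
                              recomb_probs = c(C = 0.3, Y = 0.3, R = 0.3,
                                               default = 0.1),
                              clone_size_mean = 7.1,
                              clone_size_sd = 4.6,
                              clone_size_max = 42,
                              elements_rate = 1.8,
                              element_spread_um = 15,
                              element_spacing_um = 150,
                              doublet_fraction = 0.20,
                              doublet_um = 6,
                              subtype_mix = c(PrA = 0.76, PiA = 0.05,
                                              heterogeneous = 0.19),
                              pia_depth = 0.03,
                              upper_size_multiplier = 1.5,
                              background_fraction = 0.85,
                              unique_rare_displays = TRUE) {
  cfg <- list(seed = as.integer(seed), n_clones = as.integer(n_clones),
              n_animals = as.integer(n_animals), stage = stage,
              slab_um = slab_um, copy_number_probs = copy_number_probs,
              recomb_probs = recomb_probs,
              clone_size_mean = clone_size_mean,
              clone_size_sd = clone_size_sd,
              clone_size_max = as.integer(clone_size_max),
              elements_rate = elements_rate,
              element_spread_um = element_spread_um,
              element_spacing_um = element_spacing_um,
              doublet_fraction = doublet_fraction, doublet_um = doublet_um,
              subtype_mix = subtype_mix, pia_depth = pia_depth,
              upper_size_multiplier = upper_size_multiplier,
              background_fraction = background_fraction,
              unique_rare_displays = isTRUE(unique_rare_displays))
  validate_generation_config(cfg)
}

#' @rdname generation_config
#' @param cfg candidate configuration list.
#' @export
validate_generation_config <- function(cfg) {
  stopifnot(cfg$n_clones >= 1, cfg$n_animals >= 1,
            length(cfg$slab_um) == 3, all(cfg$slab_um > 0),
            length(cfg$copy_number_probs) == 3,
            all(cfg$copy_number_probs >= 0),
            abs(sum(cfg$copy_number_probs) - 1) < 1e-9,
            length(cfg$recomb_probs) == 4, all(cfg$recomb_probs >= 0),
            abs(sum(cfg$recomb_probs) - 1) < 1e-9,
            cfg$clone_size_mean > 1,
            cfg$clone_size_sd^2 > cfg$clone_size_mean,
            cfg$clone_size_max >= 1,
            cfg$elements_rate >= 0, cfg$element_spread_um > 0,
            cfg$element_spacing_um > 0,
            cfg$doublet_fraction >= 0, cfg$doublet_fraction <= 1,
            cfg$doublet_um > 0,
            length(cfg$subtype_mix) == 3, all(cfg$subtype_mix >= 0),
            abs(sum(cfg$subtype_mix) - 1) < 1e-9,
            cfg$pia_depth > 0, cfg$pia_depth < 0.5,
            cfg$upper_size_multiplier >= 1,
            cfg$background_fraction >= 0, cfg$background_fraction < 1)
  if (cfg$element_spacing_um > min(cfg$slab_um)) {
    stop("impossible geometry: element spacing exceeds the slab",
         call. = FALSE)
  }
  structure(cfg, class = "generation_config")
}

# common background displays: the six single-compartment states plus three
# frequent co-labeled states (these dominate real inventories and give the
# rarity filter non-trivial work)
.BG_SINGLE <- c("C/", "Y/", "R/", "/C", "/Y", "/R")
.BG_COLABELED <- c("C/C", "Y/Y", "R/R")

#' Sample one label genotype and its color display
#'
#' Draws genomic copy numbers for the cytoplasmic and nuclear transgenes,
#' then an independent recombination outcome (one of the three FPs or the
#' default state) for every copy; the display is the pair of
#' per-compartment sets of expressed FPs. A fully default outcome is
#' resampled (a labeled cell is required).
#'
#' @param config a [generation_config()].
#' @return List with `cyto`, `nuc` (compact FP sets), `display` (canonical
#'   key), and `copies` (named integer vector).
#' @export
sample_label_genotype <- function(config) {
  repeat {
    copies <- sample(1:3, 2L, replace = TRUE, prob = config$copy_number_probs)
    draw_set <- function(k) {
      out <- sample(c("C", "Y", "R", ""), k, replace = TRUE,
                    prob = config$recomb_probs)
      fp_set(paste(out[out != ""], collapse = ";"))
    }
    cyto <- draw_set(copies[1])
    nuc <- draw_set(copies[2])
    if (nchar(cyto) + nchar(nuc) > 0L) {
      return(list(cyto = cyto, nuc = nuc,
                  display = paste0(cyto, "/", nuc),
                  copies = c(cyto = copies[1], nuc = copies[2])))
    }
  }
}

# clamp a coordinate matrix into the slab (x = ML, y = DV, z = AP)
.clamp_slab <- function(xyz, slab, margin = 0) {
  lim <- c(slab[["ml"]], slab[["dv"]], slab[["ap"]])
  for (j in 1:3) xyz[, j] <- pmin(pmax(xyz[, j], margin), lim[j] - margin)
  xyz
}

#' Sample the spatial layout of one clone
#'
#' Draws the clone's disconnected-element structure and cell positions:
#' the element count is `1 + Poisson(elements_rate)` (truncated at the
#' clone size), element centers form a chain spaced
#' `~element_spacing_um` apart with dorsoventrally elongated steps, cells
#' scatter around their element center (Gaussian,
#' `element_spread_um`), and a `doublet_fraction` of cells is converted
#' into doublet partners placed strictly closer than `doublet_um`. All
#' coordinates are kept inside the slab.
#'
#' @param config a [generation_config()].
#' @param size clone size (>= 1).
#' @param depth_region length-2 relative-depth interval for the clone
#'   center (default the full parenchyma away from the borders).
#' @return List with `xyz` (size x 3 matrix, columns x/y/z micrometers),
#'   `element_id` (integer), `doublet_partner` (integer index or `NA`),
#'   `center_depth`.
#' @export
generate_clone_geometry <- function(config, size,
                                    depth_region = c(0.08, 0.97)) {
  stopifnot(size >= 1)
  slab <- config$slab_um
  names(slab) <- c("dv", "ml", "ap")
  margin <- min(50, min(slab) / 10)
  center_depth <- runif(1, depth_region[1], depth_region[2])
  center <- c(runif(1, margin, slab[["ml"]] - margin),
              center_depth * slab[["dv"]],
              runif(1, margin, slab[["ap"]] - margin))
  n_elem <- min(size, 1L + rpois(1, config$elements_rate))
  centers <- matrix(NA_real_, n_elem, 3)
  centers[1, ] <- center
  if (n_elem > 1L) {
    for (k in 2:n_elem) {
      dir <- rnorm(3) * c(0.4, 1, 0.4) # DV-elongated anisotropy
      dir <- dir / sqrt(sum(dir^2))
      step <- config$element_spacing_um * runif(1, 0.8, 1.2)
      centers[k, ] <- centers[k - 1L, ] + dir * step
    }
    centers <- .clamp_slab(centers, slab, margin)
  }
  # every element gets one cell, remaining cells spread uniformly
  elem_id <- c(seq_len(n_elem),
               if (size > n_elem) sample(n_elem, size - n_elem, replace = TRUE))
  elem_id <- sort(elem_id)
  xyz <- centers[elem_id, , drop = FALSE] +
    matrix(rnorm(3 * size, sd = config$element_spread_um), size, 3)
  xyz <- .clamp_slab(xyz, slab, 1)
  partner <- rep(NA_integer_, size)
  n_pairs <- if (size >= 2) rbinom(1, floor(size / 2), config$doublet_fraction) else 0L
  if (n_pairs > 0L) {
    chosen <- sample(size, 2L * n_pairs)
    for (p in seq_len(n_pairs)) {
      a <- chosen[2L * p - 1L]; b <- chosen[2L * p]
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      xyz[b, ] <- xyz[a, ] + u * runif(1, 1.5, 0.9 * config$doublet_um)
      elem_id[b] <- elem_id[a]
      partner[a] <- b; partner[b] <- a
    }
    xyz <- .clamp_slab(xyz, slab, 0)
  }
  list(xyz = unname(xyz), element_id = as.integer(elem_id),
       doublet_partner = partner, center_depth = center_depth)
}

# truncated negative binomial clone size
.sample_clone_size <- function(mu, sd, max_size) {
  nb_size <- mu^2 / max(sd^2 - mu, 1e-6)
  repeat {
    s <- rnbinom(1, size = nb_size, mu = mu)
    if (s >= 1 && s <= max_size) return(s)
  }
}

#' Generate a synthetic labeled-cortex dataset with ground truth
#'
#' Composes the label-genotype and clone-geometry samplers into a full
#' dataset: `n_clones` clones with negative-binomial sizes (upper-half
#' clones larger by `upper_size_multiplier`), per-clone subtype
#' composition, shared per-clone displays (recombination happens in the
#' progenitor, so all sister cells inherit one display), plus background
#' cells bearing common displays, inside flat-slab cortical geometry
#' (pia at y = 0). Deterministic given `config$seed`.
#'
#' @param config a [generation_config()].
#' @return List of class `synthetic_dataset`:
#'   \describe{
#'     \item{cells}{cell table (see [cell_table()]) of clonal + background
#'       cells.}
#'     \item{truth}{list with `cells` (per-cell `clone_id`, `element_id`,
#'       `doublet_partner`) and `clones` (per-clone display, size, element
#'       count, depth, composition class, doublet cells).}
#'     \item{frame}{the flat [cortical_frame()] of the slab.}
#'     \item{config}{the resolved configuration.}
#'   }
#' @export
generate_dataset <- function(config = generation_config()) {
  config <- validate_generation_config(config)
  set.seed(config$seed)
  slab <- config$slab_um
  names(slab) <- c("dv", "ml", "ap")
  animals <- sprintf("A%02d", rep_len(seq_len(config$n_animals),
                                      config$n_clones))
  classes <- sample(names(config$subtype_mix), config$n_clones,
                    replace = TRUE, prob = config$subtype_mix)
  # overall-mean-preserving upper/lower size effect
  p_upper <- sum(config$subtype_mix[c("PiA", "heterogeneous")]) +
    config$subtype_mix[["PrA"]] *
      max(0, min(1, (0.5 - 0.08) / (0.97 - 0.08)))
  base_mean <- config$clone_size_mean /
    (1 + p_upper * (config$upper_size_multiplier - 1))

  rare_pool <- setdiff(
    with(enumerate_theoretical_combinations(3),
         states$display[nchar(states$cyto) > 0 & nchar(states$nuc) > 0]),
    .BG_COLABELED
  )
  per_animal_count <- table(animals)
  if (config$unique_rare_displays &&
      any(per_animal_count > length(rare_pool))) {
    stop("cannot give >", length(rare_pool), " clones per animal unique ",
         "displays; increase n_animals", call. = FALSE)
  }
  display_of <- character(config$n_clones)
  if (config$unique_rare_displays) {
    for (a in names(per_animal_count)) {
      idx <- which(animals == a)
      display_of[idx] <- sample(rare_pool, length(idx))
    }
  } else {
    display_of <- vapply(seq_len(config$n_clones),
                         function(i) sample_label_genotype(config)$display,
                         character(1))
  }

  cell_rows <- list()
  clone_rows <- list()
  truth_rows <- list()
  for (i in seq_len(config$n_clones)) {
    cls <- classes[i]
    depth_region <- switch(cls,
      PrA = c(0.08, 0.97),
      PiA = c(0.005, config$pia_depth - 0.002),
      heterogeneous = c(0.08, 0.33))
    # decide depth before size so the upper multiplier can apply
    geo_depth <- runif(1, depth_region[1], depth_region[2])
    mult <- if (geo_depth < 0.5) config$upper_size_multiplier else 1
    size <- .sample_clone_size(base_mean * mult, config$clone_size_sd,
                               config$clone_size_max)
    geo <- generate_clone_geometry(config, size,
                                   depth_region = c(geo_depth, geo_depth))
    subtype <- rep("PrA", size)
    if (cls == "PiA") {
      subtype[] <- "PiA"
      geo$xyz[, 2] <- runif(size, 0.003, config$pia_depth - 0.002) *
        slab[["dv"]]
    } else if (cls == "heterogeneous") {
      n_pia <- max(1L, round(runif(1, 0.2, 0.4) * size))
      pia_cells <- seq_len(n_pia) # first cell of each element first
      subtype[pia_cells] <- "PiA"
      geo$xyz[pia_cells, 2] <- runif(n_pia, 0.003,
                                     config$pia_depth - 0.002) * slab[["dv"]]
    }
    if (cls != "PrA" && any(!is.na(geo$doublet_partner))) {
      # re-appose doublet partners that the pial relocation may have split
      for (a in which(!is.na(geo$doublet_partner))) {
        b <- geo$doublet_partner[a]
        if (b > a) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          geo$xyz[b, ] <- geo$xyz[a, ] + u * runif(1, 1.5,
                                                   0.9 * config$doublet_um)
          subtype[b] <- subtype[a]
        }
      }
      geo$xyz <- .clamp_slab(geo$xyz, slab, 0)
    }
    cid <- sprintf("T%03d", i)
    ids <- sprintf("%s_%s_%02d", animals[i], cid, seq_len(size))
    cell_rows[[i]] <- data.frame(
      cell_id = ids, animal_id = animals[i], stage = config$stage,
      x_um = geo$xyz[, 1], y_um = geo$xyz[, 2], z_um = geo$xyz[, 3],
      cyto_display = parse_display(display_of[i])$cyto,
      nuc_display = parse_display(display_of[i])$nuc,
      subtype = subtype, stringsAsFactors = FALSE
    )
    truth_rows[[i]] <- data.frame(
      cell_id = ids, clone_id = cid, element_id = geo$element_id,
      doublet_partner = ifelse(is.na(geo$doublet_partner), NA_character_,
                               ids[geo$doublet_partner]),
      stringsAsFactors = FALSE
    )
    clone_rows[[i]] <- data.frame(
      clone_id = cid, animal_id = animals[i], display = display_of[i],
      size = size, n_elements = max(geo$element_id),
      center_depth = geo_depth, composition_class = cls,
      n_doublet_cells = sum(!is.na(geo$doublet_partner)),
      upper = geo_depth < 0.5, stringsAsFactors = FALSE
    )
  }
  clonal <- do.call(rbind, cell_rows)
  truth_cells <- do.call(rbind, truth_rows)
  clones <- do.call(rbind, clone_rows)

  n_bg <- round(nrow(clonal) * config$background_fraction /
                  (1 - config$background_fraction))
  if (n_bg > 0) {
    bg_disp <- sample(c(.BG_SINGLE, .BG_COLABELED), n_bg, replace = TRUE,
                      prob = c(rep(2 / 3 / 6, 6), rep(1 / 3 / 3, 3)))
    bg_parsed <- parse_display(bg_disp)
    bg <- data.frame(
      cell_id = sprintf("BG_%04d", seq_len(n_bg)),
      animal_id = sample(sprintf("A%02d", seq_len(config$n_animals)),
                         n_bg, replace = TRUE),
      stage = config$stage,
      x_um = runif(n_bg, 0, slab[["ml"]]),
      y_um = runif(n_bg, 0, slab[["dv"]]),
      z_um = runif(n_bg, 0, slab[["ap"]]),
      cyto_display = bg_parsed$cyto, nuc_display = bg_parsed$nuc,
      subtype = "unknown", stringsAsFactors = FALSE
    )
    all_cells <- rbind(clonal, bg)
    truth_cells <- rbind(truth_cells, data.frame(
      cell_id = bg$cell_id, clone_id = NA_character_,
      element_id = NA_integer_, doublet_partner = NA_character_,
      stringsAsFactors = FALSE
    ))
  } else {
    all_cells <- clonal
  }
  cells <- cell_table(
    cell_id = all_cells$cell_id, animal_id = all_cells$animal_id,
    stage = all_cells$stage, x_um = all_cells$x_um, y_um = all_cells$y_um,
    z_um = all_cells$z_um, cyto = all_cells$cyto_display,
    nuc = all_cells$nuc_display, subtype = all_cells$subtype
  )
  frame <- cortical_frame(
    pial = cbind(x = c(0, slab[["ml"]]), y = c(0, 0)),
    ventricular = cbind(x = c(0, slab[["ml"]]),
                        y = c(slab[["dv"]], slab[["dv"]]))
  )
  structure(list(cells = cells,
                 truth = list(cells = truth_cells, clones = clones),
                 frame = frame, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d cells (%d clonal in %d clones,",
                     " %d background), %d animal(s), stage %s, seed %d\n"),
              nrow(x$cells), sum(!is.na(x$truth$cells$clone_id)),
              nrow(x$truth$clones),
              sum(is.na(x$truth$cells$clone_id)),
              x$config$n_animals, x$config$stage, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `cells.csv` (the cell table), `truth.json` (ground truth), and
#' `config-resolved.yaml` (the resolved generator configuration).
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  cfg <- unclass(dataset$config)
  cfg$slab_um <- as.list(cfg$slab_um)
  yaml::write_yaml(cfg, file.path(dir, "config-resolved.yaml"))
  invisible(dir)
}
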