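test_that("combination enumeration matches the combinatorial label space", {
  expect_equal(enumerate_theoretical_combinations(3)$count, 63)
  expect_equal(enumerate_theoretical_combinations(0)$count, 0)
  # 1 copy each: (subsets of size <= 1)^2 minus the empty/empty pair
  expect_equal(enumerate_theoretical_combinations(1)$count, 4 * 4 - 1)
  # monotone, saturating at 3 copies (set semantics over 3 FPs)
  counts <- vapply(0:5,
                   function(m) enumerate_theoretical_combinations(m)$count,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[4:6], rep(63, 3))
  # states are unique canonical keys and never fully default
  st <- enumerate_theoretical_combinations(2)$states
  expect_false(anyDuplicated(st$display) > 0)
  expect_false("/" %in% st$display)
  expect_error(enumerate_theoretical_combinations(-1))
})

test_that("display keys are canonical set encodings", {
  expect_equal(display_key("Y;C", "R"), "CY/R")
  expect_equal(display_key("", "R"), "/R")
  expect_equal(display_key("RYC", ""), "CYR/")
  expect_equal(display_key("C;C", "Y"), "C/Y") # duplicate-free
  expect_error(fp_set("X"), "unknown fluorescent protein")
  expect_identical(parse_display("CY/R"),
                   data.frame(cyto = "CY", nuc = "R",
                              stringsAsFactors = FALSE))
  expect_true(display_is_colabeled("C/R"))
  expect_false(display_is_colabeled("CY/"))
  expect_true(display_is_labeled("CY/"))
})

test_that("display frequencies count and normalize correctly", {
  cells <- make_cells(matrix(rnorm(12), 4, 3), display = "Y/Y")
  f <- tabulate_display_frequencies(cells)
  expect_equal(f$fraction, 1.0)
  expect_equal(attr(f, "total_cells"), 4L)

  xyz <- matrix(rnorm(12), 4, 3)
  cells <- rbind(make_cells(xyz[1:3, ], display = "C/Y", ids = paste0("a", 1:3)),
                 make_cells(xyz[4, , drop = FALSE], display = "R/R", ids = "b1"))
  f <- tabulate_display_frequencies(cells)
  expect_equal(f$fraction[f$display == "C/Y"], 0.75)
  expect_equal(f$fraction[f$display == "R/R"], 0.25)
  expect_equal(f$display, sort(f$display)) # deterministic ordering
  expect_error(tabulate_display_frequencies(cells[0, ]), "no labeled cells")
})

test_that("frequencies of sampled genotypes agree with a direct tally", {
  cfg <- generation_config(seed = 5)
  set.seed(99)
  keys <- vapply(1:200, function(i) sample_label_genotype(cfg)$display,
                 character(1))
  cells <- make_cells(matrix(rnorm(600), 200, 3), ids = sprintf("s%03d", 1:200))
  cells$display <- keys
  p <- parse_display(keys)
  cells$cyto_display <- p$cyto
  cells$nuc_display <- p$nuc
  f <- tabulate_display_frequencies(cells)
  # independent tally oracle
  tally <- table(keys)
  expect_equal(setNames(f$n, f$display),
               setNames(as.integer(tally), names(tally)))
  expect_equal(sum(f$fraction), 1, tolerance = 1e-9)
})

test_that("per-animal scope inventories each animal separately", {
  xyz <- matrix(runif(30, 0, 100), 10, 3)
  cells <- rbind(
    make_cells(xyz[1:6, ], display = "C/Y", animal = "A1", ids = paste0("a", 1:6)),
    make_cells(xyz[7:10, ], display = "R/R", animal = "A2", ids = paste0("b", 1:4))
  )
  f <- tabulate_display_frequencies(cells, scope = "per_animal")
  expect_setequal(unique(f$animal_id), c("A1", "A2"))
  expect_true(all(f$fraction == 1))
  rare <- select_rare_displays(f, threshold = 0.5)
  expect_true(is.data.frame(rare) && nrow(rare) == 0)
})

test_that("rarity selection is strict and requires co-labeling", {
  freq <- data.frame(
    display = c("C/Y", "CY/R", "R/R", "CY/"),
    cyto = c("C", "CY", "R", "CY"), nuc = c("Y", "R", "R", ""),
    n = c(50, 49, 2, 1), fraction = c(0.50, 0.49, 0.02, 0.01),
    stringsAsFactors = FALSE
  )
  attr(freq, "scope") <- "pooled"
  # 0.02 is excluded (strict <), single-compartment excluded by criterion
  expect_identical(select_rare_displays(freq, 0.02), character(0))
  freq$fraction <- c(0.50, 0.48, 0.01, 0.01)
  expect_identical(select_rare_displays(freq, 0.02), "R/R")
})

test_that("rare-display selection is antitone in the threshold", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    fr <- runif(n); fr <- fr / sum(fr)
    st <- enumerate_theoretical_combinations(3)$states
    pick <- st[sample(nrow(st), n), ]
    freq <- data.frame(display = pick$display, cyto = pick$cyto,
                       nuc = pick$nuc, n = 1L, fraction = fr,
                       stringsAsFactors = FALSE)
    attr(freq, "scope") <- "pooled"
    thr <- sort(runif(3, 0.01, 0.5))
    sel <- lapply(thr, function(t) select_rare_displays(freq, t))
    expect_true(all(sel[[1]] %in% sel[[2]]))
    expect_true(all(sel[[2]] %in% sel[[3]]))
  }
})

test_that("clone calling follows the single-linkage contract", {
  # two same-display cells 100 um apart: one clone
  cs <- call_clones(make_cells(rbind(c(0, 0, 0), c(0, 100, 0))), "CY/R")
  expect_equal(nrow(cs$clones), 1)
  expect_equal(cs$clones$n_cells, 2)
  # 700 um apart: two singleton clones
  cs <- call_clones(make_cells(rbind(c(0, 0, 0), c(0, 700, 0))), "CY/R")
  expect_equal(nrow(cs$clones), 2)
  expect_equal(cs$clones$n_cells, c(1, 1))
  # exactly 600 um: strict "<" means separate clones
  cs <- call_clones(make_cells(rbind(c(0, 0, 0), c(0, 600, 0))), "CY/R")
  expect_equal(nrow(cs$clones), 2)
  # chain 0/400/800: one clone of 3, diameter violation flagged
  cs <- call_clones(make_cells(rbind(c(0, 0, 0), c(0, 400, 0), c(0, 800, 0))),
                    "CY/R")
  expect_equal(nrow(cs$clones), 1)
  expect_equal(cs$clones$n_cells, 3)
  expect_true(cs$clones$diameter_flag)
  expect_equal(cs$clones$max_pairwise_um, 800)
})

test_that("clone calling partitions within animal/stage/display groups", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 0, 0), c(10, 0, 0))
  cells <- rbind(
    make_cells(xyz[1:2, ], display = "C/Y", animal = "A1", ids = c("p1", "p2")),
    make_cells(xyz[3:4, ], display = "C/Y", animal = "A2", ids = c("q1", "q2"))
  )
  cs <- call_clones(cells, "C/Y")
  expect_equal(nrow(cs$clones), 2) # same display, same place, two animals
  expect_equal(sort(cs$clones$animal_id), c("A1", "A2"))
  # non-rare displays stay unassigned
  cs2 <- call_clones(cells, character(0))
  expect_true(all(is.na(cs2$cells$clone_id)))
  expect_equal(nrow(cs2$clones), 0)
})

test_that("clone calling is invariant to row order and rigid translation", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    xyz <- cbind(runif(n, 0, 1500), runif(n, 0, 1500), runif(n, 0, 1500))
    disp <- sample(c("C/Y", "CY/R", "R/CY"), n, replace = TRUE)
    cells <- make_cells(xyz, ids = sprintf("c%02d", 1:n))
    cells$display <- disp
    p <- parse_display(disp)
    cells$cyto_display <- p$cyto; cells$nuc_display <- p$nuc
    rare <- c("C/Y", "CY/R", "R/CY")
    base <- call_clones(cells, rare)
    # shuffled rows
    perm <- sample(n)
    shuf <- call_clones(cells[perm, ], rare)
    m <- match(base$cells$cell_id, shuf$cells$cell_id)
    expect_equal(base$cells$clone_id, shuf$cells$clone_id[m])
    # rigid translation
    cells2 <- cells
    cells2$x_um <- cells2$x_um + 1e4
    cells2$y_um <- cells2$y_um - 5e3
    cells2$z_um <- cells2$z_um + 123.4
    trans <- call_clones(cells2, rare)
    expect_equal(base$cells$clone_id, trans$cells$clone_id)
  }
})

test_that("invalid coordinates are rejected with the offending cell named", {
  cells <- make_cells(rbind(c(0, 0, 0), c(1, 1, 1)), ids = c("ok1", "bad2"))
  cells$y_um[2] <- NaN
  expect_error(call_clones(cells, "CY/R"), "bad2")
})

test_that("section-indexed z is converted via the section thickness", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    cell_id = c("a", "b"), animal_id = "A1", stage = "P7",
    x_um = c(0, 0), y_um = c(0, 10), z = c(1, 3), z_unit = "section",
    cyto_display = "C;Y", nuc_display = "R"
  ), f, row.names = FALSE)
  cells <- read_cells(f, section_thickness_um = 80)
  expect_equal(cells$z_um, c(80, 240))
  expect_equal(cells$display, rep("CY/R", 2))
  expect_true(attr(cells, "z_is_section"))
  # mixed units are an error
  write.csv(data.frame(
    cell_id = c("a", "b"), animal_id = "A1", stage = "P7",
    x_um = 0, y_um = 0, z = c(1, 3), z_unit = c("um", "section"),
    cyto_display = "C", nuc_display = "R"
  ), f, row.names = FALSE)
  expect_error(read_cells(f), "mixed z units")
})
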