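test_that("axis extents are per-axis ranges", {
  expect_equal(axis_extents(matrix(c(5, 5, 5), 1, 3)),
               c(extent_dv = 0, extent_ml = 0, extent_ap = 0))
  expect_equal(axis_extents(rbind(c(0, 0, 0), c(0, 100, 0))),
               c(extent_dv = 100, extent_ml = 0, extent_ap = 0))
  set.seed(3)
  xyz <- matrix(rnorm(30, sd = 50), 10, 3)
  ext <- axis_extents(xyz)
  expect_equal(unname(ext["extent_ml"]), max(xyz[, 1]) - min(xyz[, 1]))
  expect_equal(unname(ext["extent_dv"]), max(xyz[, 2]) - min(xyz[, 2]))
  expect_equal(unname(ext["extent_ap"]), max(xyz[, 3]) - min(xyz[, 3]))
})

test_that("Delaunay edges: regular tetrahedron and pairwise fallbacks", {
  a <- 10
  tet <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
               c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  d <- delaunay_edge_lengths(tet)
  expect_false(d$fallback)
  expect_equal(d$lengths, rep(a, 6), tolerance = 1e-9)
  # two cells: pairwise fallback
  d2 <- delaunay_edge_lengths(rbind(c(0, 0, 0), c(0, 50, 0)))
  expect_true(d2$fallback)
  expect_equal(d2$lengths, 50)
  # coplanar points: fallback
  d3 <- delaunay_edge_lengths(cbind(runif(5), runif(5), 0))
  expect_true(d3$fallback)
  expect_equal(length(d3$lengths), choose(5, 2))
  expect_error(delaunay_edge_lengths(matrix(0, 1, 3)), "singleton")
})

test_that("Delaunay edge multiset matches the qhull oracle in general position", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    xyz <- matrix(runif(3 * n, 0, 100), n, 3)
    mine <- delaunay_edge_lengths(xyz)
    expect_false(mine$fallback)
    oracle <- scipy_delaunay_edge_lengths(xyz)
    expect_equal(mine$lengths, oracle, tolerance = 1e-8)
  }
})

test_that("Delaunay on a degenerate (cospherical) cube is a valid triangulation", {
  cube <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  d <- delaunay_edge_lengths(cube)
  expect_false(d$fallback)
  # all 12 sides present; every edge is a side, face diagonal or space diagonal
  expect_equal(sum(abs(d$lengths - 10) < 1e-6), 12)
  cls <- vapply(d$lengths, function(l) {
    min(abs(l - c(10, 10 * sqrt(2), 10 * sqrt(3))))
  }, numeric(1))
  expect_true(all(cls < 1e-6))
  # edge bounds: max <= diameter, min >= min pairwise distance
  expect_lte(max(d$lengths), 10 * sqrt(3) + 1e-9)
  expect_gte(min(d$lengths), 10 - 1e-9)
})

test_that("convex hull volume is exact on canonical solids", {
  simplex <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h <- convex_hull_volume(simplex)
  expect_equal(h$volume, 1 / 6)
  expect_false(h$degenerate)
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  expect_equal(convex_hull_volume(cube)$volume, 1000)
  # coplanar and small inputs are degenerate with volume 0
  expect_equal(convex_hull_volume(cbind(runif(4), runif(4), 1)),
               list(volume = 0, degenerate = TRUE))
  expect_equal(convex_hull_volume(matrix(0, 1, 3))$degenerate, TRUE)
})

test_that("convex hull volume matches the qhull oracle and scales cubically", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(6:15, 1)
    xyz <- matrix(rnorm(3 * n, sd = 40), n, 3)
    v <- convex_hull_volume(xyz)$volume
    expect_equal(v, scipy_hull_volume(xyz), tolerance = 1e-8)
    # interior points do not change the hull
    withint <- rbind(xyz, colMeans(xyz))
    expect_equal(convex_hull_volume(withint)$volume, v, tolerance = 1e-9)
    # rigid translation invariance, cubic scaling, bounding-box bound
    expect_equal(convex_hull_volume(sweep(xyz, 2, c(100, -50, 3)))$volume,
                 v, tolerance = 1e-8)
    expect_equal(convex_hull_volume(xyz * 2)$volume, 8 * v, tolerance = 1e-8)
    expect_lte(v, prod(apply(xyz, 2, function(u) diff(range(u)))))
  }
})

test_that("element decomposition matches brute-force connected components", {
  # worked example: cells at y = 0, 10, 50 with threshold 20
  xyz <- rbind(c(0, 0, 0), c(0, 10, 0), c(0, 50, 0))
  rownames(xyz) <- c("a", "b", "c")
  e <- decompose_elements(xyz, 20)
  expect_equal(e$n_elements, 2)
  expect_equal(e$clustered_cells, 2)
  expect_setequal(vapply(e$elements, paste, collapse = "+", ""),
                  c("a+b", "c"))
  # singleton clone: one element, nothing clustered
  s <- decompose_elements(matrix(0, 1, 3), 20)
  expect_equal(s$n_elements, 1)
  expect_equal(s$clustered_cells, 0)
  # randomized equivalence with an independent BFS oracle
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(2:25, 1)
    xyz <- matrix(runif(3 * n, 0, 300), n, 3)
    thr <- runif(1, 10, 150)
    e <- decompose_elements(xyz, thr)
    oracle <- bfs_components(xyz, thr, strict = FALSE)
    expect_equal(e$n_elements, max(oracle))
    sizes <- table(oracle)
    expect_equal(e$clustered_cells, sum(sizes[sizes >= 2]))
  }
})

test_that("element count is monotone in the threshold with correct limits", {
  set.seed(31)
  xyz <- matrix(runif(36, 0, 200), 12, 3)
  thr <- sort(runif(6, 1, 400))
  ns <- vapply(thr, function(t) decompose_elements(xyz, t)$n_elements,
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(decompose_elements(xyz, 1e9)$n_elements, 1)
  expect_equal(decompose_elements(xyz, 1e-9)$n_elements, 12)
})

test_that("doublet detection uses strict proximity and component size 2", {
  two <- rbind(c(0, 0, 0), c(0, 5, 0))
  d <- detect_doublets(two, 6)
  expect_equal(length(d$doublets), 1)
  expect_equal(d$n_doublet_cells, 2)
  # exactly 6 um apart: NOT a doublet ("closer than")
  d6 <- detect_doublets(rbind(c(0, 0, 0), c(0, 6, 0)), 6)
  expect_equal(length(d6$doublets), 0)
  # three mutually close cells: a multiplet, not doublets
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  d3 <- detect_doublets(tri, 6)
  expect_equal(length(d3$doublets), 0)
  expect_equal(length(d3$multiplets), 1)
  expect_equal(lengths(d3$multiplets), 3)
})

test_that("doublet pairs are contained in element clusters", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    xyz <- matrix(runif(3 * n, 0, 60), n, 3)
    rownames(xyz) <- paste0("c", seq_len(n))
    dbl <- detect_doublets(xyz, 6)
    elems <- decompose_elements(xyz, 40)
    clustered <- unlist(elems$elements[lengths(elems$elements) >= 2])
    for (pair in dbl$doublets) expect_true(all(pair %in% clustered))
  }
})

test_that("relative depth interpolates between the boundary polylines", {
  fr <- flat_frame(1000)
  expect_equal(relative_depth(100, 0, fr), 0)
  expect_equal(relative_depth(100, 1000, fr), 1)
  expect_equal(relative_depth(500, 250, fr), 0.25)
  # slanted pia: depth follows the local thickness
  fr2 <- cortical_frame(pial = cbind(c(0, 1000), c(0, 200)),
                        ventricular = cbind(c(0, 1000), c(1000, 1000)))
  expect_equal(relative_depth(500, 100 + 0.5 * 900, fr2), 0.5)
  expect_error(relative_depth(100, 2000, fr, cell_id = "deep1"), "deep1")
  expect_error(cortical_frame(pial = cbind(c(0, 1), c(10, 10)),
                              ventricular = cbind(c(0, 1), c(0, 0))),
               "below")
})

test_that("clone depth summary: barycenter, U/L class and binning", {
  s <- clone_depth_summary(c(0.2, 0.4))
  expect_equal(s$barycenter_depth, 0.3)
  expect_equal(s$upper_lower, "U")
  s2 <- clone_depth_summary(c(0.5, 0.9))
  expect_equal(s2$barycenter_depth, 0.7)
  expect_equal(s2$upper_lower, "L")
  # bin 1 at the pial surface; depth 1.0 clamps into the last bin
  expect_equal(clone_depth_summary(c(0, 0.17, 0.5, 1.0), n_bins = 6)$bin_index,
               c(1L, 2L, 4L, 6L))
})

test_that("relative dispersion is thickness-normalized and scale invariant", {
  fr <- flat_frame(1000)
  xyz <- rbind(c(500, 100, 0), c(500, 300, 0), c(510, 150, 0), c(490, 250, 0))
  expect_equal(relative_dispersion(xyz, fr, "DV"), (200 / 1000 * 100) / 4)
  expect_equal(relative_dispersion(xyz[1, , drop = FALSE], fr, "DV"), 0)
  # doubling coordinates and the frame leaves the value unchanged
  fr2 <- flat_frame(2000, width = 4000)
  expect_equal(relative_dispersion(xyz * 2, fr2, "DV"),
               relative_dispersion(xyz, fr, "DV"))
  expect_equal(relative_dispersion(xyz, fr, "ML"), (20 / 1000 * 100) / 4)
})

test_that("pair distances pick marker-positive cells within clones", {
  cells <- make_cells(rbind(c(0, 0, 0), c(3, 4, 0), c(200, 0, 0)),
                      ids = c("e1", "e2", "e3"))
  cells$edu <- c(TRUE, TRUE, FALSE)
  cs <- call_clones(cells, "CY/R")
  pd <- pair_distances(cs, "edu")
  expect_equal(nrow(pd), 1)
  expect_equal(pd$distance_um, 5)
  expect_false(pd$multiway)
  # no positives: empty result
  cells$edu <- FALSE
  expect_equal(nrow(pair_distances(call_clones(cells, "CY/R"), "edu")), 0)
  # three positives in one clone: all three pairwise distances, flagged
  cells2 <- make_cells(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                       ids = paste0("t", 1:3))
  cells2$edu <- TRUE
  pd3 <- pair_distances(call_clones(cells2, "CY/R"), "edu")
  expect_equal(nrow(pd3), 3)
  expect_true(all(pd3$multiway))
})

test_that("spatial statistics respect rigid motions and isotropic scaling", {
  set.seed(13)
  xyz <- matrix(runif(24, 0, 200), 8, 3)
  base_del <- delaunay_edge_lengths(xyz)
  base_hull <- convex_hull_volume(xyz)$volume
  shift <- sweep(xyz, 2, c(1000, -200, 55))
  expect_equal(delaunay_edge_lengths(shift)$lengths, base_del$lengths,
               tolerance = 1e-8)
  expect_equal(axis_extents(shift), axis_extents(xyz), tolerance = 1e-9)
  sc <- xyz * 3
  expect_equal(delaunay_edge_lengths(sc)$lengths, 3 * base_del$lengths,
               tolerance = 1e-8)
  expect_equal(convex_hull_volume(sc)$volume, 27 * base_hull,
               tolerance = 1e-8)
})
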