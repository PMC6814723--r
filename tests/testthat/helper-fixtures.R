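# Fixture builders and independent oracles shared across the suite.

# quick cell table at given coordinates, one display for all cells
make_cells <- function(xyz, display = "CY/R", animal = "A1", stage = "P7",
                       ids = NULL, subtype = "PrA") {
  xyz <- as.matrix(xyz)
  p <- clonoscope::parse_display(display)
  clonoscope::cell_table(
    cell_id = ids %||% sprintf("c%03d", seq_len(nrow(xyz))),
    animal_id = animal, stage = stage,
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    cyto = p$cyto, nuc = p$nuc, subtype = subtype
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat slab frame: pia at y = 0, ventricle at y = thickness
flat_frame <- function(thickness = 1000, width = 2000) {
  clonoscope::cortical_frame(
    pial = cbind(x = c(0, width), y = c(0, 0)),
    ventricular = cbind(x = c(0, width), y = c(thickness, thickness))
  )
}

# write an SWC file from a node data frame (id type x y z radius parent)
write_swc_fixture <- function(nodes, path = tempfile(fileext = ".swc")) {
  writeLines(c("# synthetic test arbor",
               apply(nodes, 1L, paste, collapse = " ")), path)
  path
}

# --- independent oracles ---------------------------------------------------

# connected components by breadth-first search over an explicit distance
# matrix (independent of the igraph-based implementation)
bfs_components <- function(xyz, threshold, strict = TRUE) {
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  adj <- if (strict) d < threshold else d <= threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# scipy/qhull geometry oracle (python is on the PATH of this toolchain)
run_scipy <- function(script, xyz) {
  csv <- apply(as.matrix(xyz), 1L, paste, collapse = ",")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), input = csv,
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("python oracle failed")
  out
}

scipy_hull_volume <- function(xyz) {
  out <- run_scipy(paste0(
    "import sys, numpy as np\n",
    "from scipy.spatial import ConvexHull\n",
    "pts = np.loadtxt(sys.stdin, delimiter=',')\n",
    "print('%.17g' % float(ConvexHull(pts).volume))\n"), xyz)
  as.numeric(out[length(out)])
}

scipy_delaunay_edge_lengths <- function(xyz) {
  out <- run_scipy(paste0(
    "import sys, numpy as np\n",
    "from scipy.spatial import Delaunay\n",
    "pts = np.loadtxt(sys.stdin, delimiter=',')\n",
    "tri = Delaunay(pts)\n",
    "edges = set()\n",
    "for s in tri.simplices:\n",
    "    s = sorted(s)\n",
    "    for i in range(4):\n",
    "        for j in range(i + 1, 4):\n",
    "            edges.add((s[i], s[j]))\n",
    "ls = sorted(float(np.linalg.norm(pts[i] - pts[j])) for i, j in edges)\n",
    "print(','.join('%.17g' % x for x in ls))\n"), xyz)
  as.numeric(strsplit(out[length(out)], ",")[[1]])
}

# independent branch-decomposition oracle: recursive traversal over an
# adjacency list, counting event-to-event paths
oracle_branch_count <- function(nodes) {
  kids <- split(nodes$id[nodes$parent != -1], nodes$parent[nodes$parent != -1])
  n_children <- function(id) length(kids[[as.character(id)]])
  root <- nodes$id[nodes$parent == -1]
  count <- 0L
  walk <- function(id) {
    ch <- kids[[as.character(id)]]
    for (c0 in ch) {
      count <<- count + 1L # a branch starts here
      v <- c0
      while (n_children(v) == 1L) v <- kids[[as.character(v)]]
      if (n_children(v) >= 2L) walk(v)
    }
  }
  walk(root)
  count
}

# adjusted Rand index between two labelings over the same cells, treating
# NA in `called` as singleton clusters
ari_vs_truth <- function(truth, called) {
  keep <- !is.na(truth)
  truth <- truth[keep]; called <- called[keep]
  called[is.na(called)] <- paste0(".un", seq_len(sum(is.na(called))))
  mclust::adjustedRandIndex(truth, called)
}
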