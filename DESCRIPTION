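Package: clonoscope
Title: Clonal Analysis of Combinatorially Labeled Cortical Astrocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identification and 3D spatial analysis of astrocyte clones
    labeled with combinatorial multicolor (Brainbow-type) markers.
    Inventories cytoplasmic/nuclear fluorescent-protein color displays,
    selects rare combinations, calls clones by shared display and spatial
    single linkage, and computes clone-level spatial statistics: axis
    extents, Delaunay-triangulation dispersion, convex-hull volumes,
    decomposition into disconnected elements, doublet detection, cortical
    depth normalization and binning, and principal-axis orientation with a
    uniform-rotation null. Also extracts arbor morphometry from SWC
    reconstructions, ships a calibrated synthetic-data generator with full
    ground truth, and provides an end-to-end pipeline with nonparametric
    group comparisons (Mann-Whitney, Kruskal-Wallis with Dunn post hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
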