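# clonoscope

Clonal analysis of combinatorially labeled cortical astrocytes.

In multicolor (Brainbow-type) lineage tracing, cortical progenitors are
electroporated with two transposable transgenes that, after Cre
recombination, stochastically express one of three fluorescent proteins
(cyan, yellow, red) in the **cytoplasm** or the **nucleus**. Because
recombination and genomic integration happen in the progenitor, all of its
descendants — a *clone* — inherit the same combinatorial *color display*:
the pair of per-compartment FP sets. With 1–3 copies of each transgene, 63
distinguishable displays exist; the rare ones act as heritable clonal
barcodes. `clonoscope` implements the complete downstream analysis for
such experiments, for developmental biologists quantifying glial (or other)
clonal architecture from pointed cell coordinates:

- **Clone identification.** Display inventory over all labeled cells;
  selection of *rare* displays (frequency < 2% among labeled cells, with
  both compartments labeled); clone calling as single-linkage connected
  components among same-display cells of one animal at 3D distance
  < 600 µm.
- **3D spatial statistics per clone.** Axis extents (DV/ML/AP), dispersion
  via the edge lengths of the 3D Delaunay triangulation, convex-hull
  volume, decomposition into disconnected *elements* (clusters of apposed
  cells vs isolated cells at a stage-specific disconnection distance),
  sister-cell *doublets* (somata closer than the 6 µm mean nuclear size),
  cortical depth normalization between pial and ventricular boundary
  polylines, six-bin depth profiles, and per-cell relative dispersion.
- **Orientation.** Principal axis of each clone by SVD of the coordinate
  covariance (`L(t) = M + tV`), folded angle to the radial (DV) direction,
  and a null distribution built from uniformly random 3D rotations of the
  observed axes (Haar measure on SO(3); under the null the angle has
  density sin θ on [0°, 90°]).
- **Arbor morphometry.** SWC reconstruction ingestion with validation and
  anisotropic rescaling; branch counts, total branch length, frustum-sum
  model volume, endings, and branch/ending densities within a convex-hull
  territory proxy.
- **Synthetic data.** A calibrated generator emulating the labeling and
  clonal-growth process (overdispersed clone sizes, multi-element layouts,
  doublets, subtype composition, common-display background) with full
  ground truth, so the whole pipeline is testable without any raw imaging
  data.
- **Statistics.** Mann–Whitney (exact where feasible) for two groups,
  Kruskal–Wallis with Dunn's multiple-comparison post hoc for three or
  more.

## Worked example

```r
library(clonoscope)

# a synthetic labeled cortex with known ground truth
ds <- generate_dataset(generation_config(seed = 1))
ds
#> <synthetic_dataset> 9807 cells (1471 clonal in 200 clones, 8336 background),
#>   5 animal(s), stage P7, seed 1

report <- run_pipeline(ds$cells, frame = ds$frame)
#> ingest: 9807 labeled cells, 5 animal(s), stage(s) P7
#> inventory: 55 distinct displays, 46 rare co-labeled (< 2%)
#> clone calling: 200 clones from 1471 assigned cells
#> orientation: mean angle 40.8 deg vs null 57.3 deg (p = 0)

print(report$aggregates, digits = 3)
#>   stage n_clones mean_size sem_size mean_n_elements sem_n_elements
#> 1    P7      200      7.36    0.362            2.42         0.0828
#>   clustered_pct doublet_pct pra_only_pct pia_only_pct heterogeneous_pct
#> 1            88        21.1           77          4.5              18.5
```

Reading the output: 9,807 labeled cells were inventoried; 46 co-labeled
displays fall below the 2% rarity cut and seed clone calling, which
recovers all 200 planted clones. Clones average 7.4 cells (± s.e.m.)
distributed over 2.4 disconnected elements; 88% of clonal cells sit in
clusters of apposed cells, 21% belong to sub-6 µm doublets, and the
protoplasmic-only / pial-only / mixed composition split is 77/4.5/18.5%.
The clone principal axes average 40.8° from the radial direction versus
57.3° for randomly rotated axes — the clones are preferentially radial
(empirical p below 1/1000 rotations).

Arbor morphometry from an SWC reconstruction:

```r
swc <- system.file("extdata", "synthetic_astrocyte.swc", package = "clonoscope")
arbor_metrics(read_swc(swc))
#> <arbor_metrics> 25 branches, 15 endings, 10 branch points
#>   total length 279.3 um, model volume 3190.9 um^3, territory (hull proxy) 9.12e+03 um^3
```

A command-line wrapper with `run`, `generate` and `arbor` subcommands is
installed at `inst/cli/clonoscope.R`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "clonoscope", load_package = "installed")'
```

The suite checks every operation against hand-computed values, analytic
laws (e.g. the sin θ rotation null), independent brute-force oracles, and
ground-truth recovery on synthetic data.

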