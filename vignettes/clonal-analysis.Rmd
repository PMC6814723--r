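---
title: "Methods: clonal analysis of combinatorially labeled astrocytes"
author: "clonoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal analysis of combinatorially labeled astrocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoscope)
```

## The measurement model

Combinatorial multicolor labeling marks a progenitor with a random,
heritable *color display*: each genomic copy of the cytoplasmic and the
nuclear transgene independently settles, after Cre recombination, into one
of three fluorescent proteins (C, Y, R) or the unrecombined default. The
observable display of a cell is the pair of per-compartment FP *sets* —
intensity ratios and copy numbers are not observable in routine imaging
and are deliberately outside the model. With up to three copies of each
transgene the reachable per-compartment sets are all subsets of
\{C, Y, R\}, so the display space holds $8 \times 8 - 1 = 63$ labeled
states (`enumerate_theoretical_combinations(3)`); with one copy of each,
$4 \times 4 - 1 = 15$.

Clone identification rests on three criteria:

1. **Co-labeling.** A clonal mark requires at least one expressed copy of
   *each* transgene: displays with an empty compartment are inventoried
   but never seed clones.
2. **Rarity.** The display's frequency among all labeled cells must be
   strictly below 2% (`select_rare_displays()`, threshold configurable).
   Rarity is computed *pooled* across the dataset's animals by default,
   matching the pooled inventories such experiments report; a per-animal
   scope is available (`rarity_scope` config key) because the scope is a
   genuine design freedom.
3. **Spatial linkage.** Same-display cells of one animal and stage are
   joined when their 3D distance is strictly below 600 µm, and each
   connected component of this graph is one clone (`call_clones()`).

The linkage rule deserves a note: a "maximal distance among sister cells"
criterion does not by itself define a grouping algorithm, and
diameter-constrained partitioning is NP-hard. We use single-linkage
connected components — deterministic, order-independent, and faithful to
the idea that a chain of sub-600 µm neighbors is one clone — and flag
components whose realized diameter reaches 600 µm (`diameter_flag`)
rather than splitting them arbitrarily. Both strict inequalities follow
the criteria's wording ("< 2%", "less than 600 µm").

## Spatial statistics

All coordinates are micrometers with `x` = mediolateral, `y` =
dorsoventral depth (increasing from pia to ventricle), `z` =
anteroposterior. Serial-section datasets carry `z` as section index ×
section thickness (default 80 µm).

* **Dispersion** (`delaunay_edge_lengths()`): the unique edge lengths of
  the 3D Delaunay triangulation of the member somata. Because no 3D
  triangulation binding exists in this R stack, the package computes the
  triangulation by exhaustive enumeration: a 4-subset is a Delaunay
  tetrahedron exactly when its circumsphere contains no other member.
  Clones span 1–42 cells, so the $O(n^5)$ enumeration is instantaneous at
  realistic sizes. Cospherical ties (lattice-like configurations) are
  broken by a deterministic, index-keyed symbolic perturbation of
  magnitude $10^{-6}$ × the coordinate range; edge lengths are always
  measured on the unperturbed coordinates. Clones of 2–3 cells and
  degenerate (collinear/coplanar) configurations fall back to all pairwise
  distances with `fallback = TRUE` — small clones are common and must not
  error. Because figures in this field do not standardize on one summary,
  the full edge list plus mean/median/max are all returned.
* **Clone volume** (`convex_hull_volume()`): exact facet-enumeration
  convex hull (supporting-plane test over point triples, 2D hull ordering
  within each face, pyramid accumulation from an interior point). Fewer
  than 4 points or affinely dependent sets return volume 0 with a
  `degenerate` flag.
* **Elements** (`decompose_elements()`): connected components at distance
  ≤ the *disconnection distance*, the stage-specific astrocyte mean
  diameter + s.d. Cells in components of size ≥ 2 are "clustered";
  singletons are isolated cells. Connectivity is inclusive (`≤`) because
  disconnection is "greater than" the threshold; doublets below use the
  strict `<` of "closer than". The per-stage distances are a required
  analysis parameter; the shipped defaults (P7 = 60 µm, P21 = 70 µm) are
  implementation defaults, not measured values, and should be overridden
  with each dataset's own morphometry.
* **Doublets** (`detect_doublets()`): components at distance < 6 µm (the
  mean astrocyte nuclear size). Only components of exactly two cells are
  doublets; larger ones are reported as multiplets so that doublet counts
  are not inflated by dense triplets.
* **Depth** (`relative_depth()`): depth = $d_\mathrm{pial} /
  (d_\mathrm{pial} + d_\mathrm{vent})$ with both distances measured along
  the DV axis against piecewise-linear pial and ventricular boundary
  polylines interpolated at the cell's ML position. This is DV ray
  casting; curved (streamline) cortical coordinates are out of scope. The
  polylines must be single-valued in ML over the region of interest.
  Cells outside the band within a 2% tolerance are clamped; farther out
  is an error naming the cell. The clone barycenter is the mean member
  depth; barycenters above mid-depth are "U"(pper), otherwise "L"(ower);
  cells fall into `n_bins = 6` equal bins with bin 1 at the pia and depth
  1.0 clamped into the last bin.
* **Relative dispersion** (`relative_dispersion()`): (axis extent ÷ local
  cortical thickness × 100) ÷ clone size, thickness evaluated at the
  clone barycenter's ML position — a per-cell, thickness-normalized
  spread that is invariant under joint rescaling of cells and frame.

## Orientation and the rotation null

`fit_principal_axis()` takes $M$ as the coordinate mean and $V$ as the
top right-singular vector of the centered coordinates (equivalently the
leading eigenvector of the coordinate covariance). The axis is unsigned;
$V$ is canonicalized to a non-negative DV component (lexicographic
tie-break at zero), and near-ties between the top two singular values set
a `degenerate` flag rather than failing. The folded angle to the radial
direction is $\arccos |V \cdot r| \in [0°, 90°]$.

`rotation_null()` asks whether observed axes are more radial than chance:
each fitted axis is rotated by independent uniform rotations (uniform
unit quaternions — Shoemake's construction — giving Haar measure on
SO(3), which makes the rotated axes uniform on the sphere). Under this
null the folded angle has density $\sin\theta$, so $E[\cos\theta] = 1/2$
and the median angle is 60°; the test suite verifies both plus the
Kolmogorov–Smirnov distance to $1 - \cos\theta$ at $10^5$ draws. As the
comparison statistic is itself a design freedom, the package uses the
pooled per-clone mean angle with an empirical p-value (fraction of
per-draw null means at or below the observed mean), with the full null
sample returned for any other summary. Defaults: 1000 rotations, seeded.

## Arbor morphometry

`read_swc()` ingests standard 7-column SWC with validation (single root,
acyclic, resolvable parents, positive radii) and optional anisotropic
rescaling to restore physical dimensions. `arbor_metrics()` follows the
usual branch-decomposition conventions: a *branch* is a maximal path
between consecutive topological events (soma exit or root, branch point,
tip); a node with $k \ge 2$ children is one branch point spawning $k$
branches (trifurcations flagged, contributing out-degree − 1 extra
branches). Model volume sums truncated cones,
$\pi h (r_1^2 + r_1 r_2 + r_2^2)/3$ per segment — the frustum choice over
cylinders is deliberate and documented since radii taper. Soma nodes
(structure code 1) are excluded from branch topology and cable length but
included in the territory hull. Branch and ending densities divide by a
*territory proxy*, the convex hull of all nodes, because true territorial
volumes come from fluorescence segmentation that this package does not
perform; externally measured volumes override the proxy and the output
flags which was used.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with full ground truth. Calibration targets are the printed
characteristics of P7 protoplasmic astrocyte clones:

| parameter | default | rationale |
|---|---|---|
| clone size law | negative binomial, mean 7.1, s.d. 4.6, truncated to 1–42 | matches the reported mean, overdispersion and observed range; no law is stated, NB is the standard overdispersed count model |
| elements per clone | 1 + Poisson(1.8), truncated at clone size | yields the reported 2–3 disconnected elements per clone |
| element spacing | 150 µm | separated elements well beyond the disconnection distance, well within the 600 µm linkage |
| element spread (s.d.) | 15 µm | clusters of *apposed* somata: typical within-cluster neighbor distance ≈ 2.26 σ ≈ 34 µm, safely below the 60 µm disconnection distance. A larger spread (e.g. 40 µm) would make planted clusters self-disconnect at 60 µm, contradicting what an "element" is |
| doublet fraction | 0.20 | reported stable ~20% of cells in doublets; planted as Binomial(⌊size/2⌋, 0.2) pairs moved to < 6 µm |
| subtype mix | 76 / 5 / 19 % | reported composition of PrA-only / PiA-only / heterogeneous clones |
| upper-half size multiplier | 1.5 | upper clones are reported larger; the base mean is rescaled by the expected upper fraction so the configured mean stays the overall expectation |
| background fraction | 0.85 | real inventories are dominated by common displays (tens of thousands of labeled cells vs thousands of clonal cells); background cells carry single-compartment and three common co-labeled displays so the rarity filter has non-trivial work |
| slab | 1400 × 2000 × 2000 µm | cortical thickness × a plausible imaged tangential extent |
| animals | 5 (for 200 clones) | only 46 co-labeled displays can serve as unique marks once common ones are excluded, so uniqueness is per animal — exactly as in the real design, where displays recur across brains; 40 clones/brain sits in the reported 36–160 range |

Pial-astrocyte cells are placed at relative depth < 0.03 (the pial
surface); heterogeneous clones are centered in the upper third so their
pial members remain within linkage distance of their parenchymal members.

What the generator does *not* emulate: imaging noise and color
misclassification, migration dynamics, anisotropic section distortion,
curved cortical geometry (the synthetic frame is a flat slab), and
intensity-resolved displays. Recovery tests on this generator therefore
validate the computational pipeline — grouping, geometry, statistics —
not the upstream image analysis.

## Numerical choices and problem sizes

Degenerate inputs return flagged values instead of errors wherever a
small clone makes them routine (singletons, pairs, coplanar clones).
Tolerances: supporting-plane and insphere tests use relative tolerances
of $10^{-9}$ on the coordinate scale; the symbolic perturbation is
$10^{-6}$ relative and deterministic (no RNG state is touched). All
stochastic components take explicit seeds; `rotation_null()` restores the
caller's RNG state.

The shipped test and verification suites use problem sizes chosen to make
every check sharp yet quick on a laptop: 200-clone datasets (~10⁴ cells)
for recovery, $10^5$ draws for rotation-null analytics, 100 replicates
for axis recovery, 1000 replicates for test calibration, and ≤ 30-point
configurations for geometry oracles.

## Known limitations

- Rarity scope (pooled vs per-animal) changes which displays seed clones
  in small datasets; the default is pooled and the choice is recorded in
  the report provenance.
- Single linkage can chain distinct biological clones that share a
  display and overlap spatially; the diameter flag marks the symptom but
  cannot resolve it — only rarer displays can.
- The depth model assumes locally single-valued boundaries along ML and
  straight DV rays; strongly curved cortex should be flattened upstream.
- Dunn's post hoc uses the normal approximation with tie correction;
  exact small-sample behavior is inherited from the rank statistics.
- The territory proxy (node convex hull) underestimates territories of
  concave arbors and is labeled as a proxy in all outputs.
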