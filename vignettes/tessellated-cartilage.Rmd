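---
title: "Quantifying and growing tessellated cartilage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and growing tessellated cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesserate)
```

## The system and the questions

The skeletons of sharks and rays are cartilage covered by a thin veneer of
small mineralized tiles — tesserae — joined by unmineralized, fiber-bridged
gaps. Because this tissue is apparently never resorbed or remodeled, a
growing animal must enlarge a continuous tiled covering purely by adding
mineral at tile margins. That raises three linked questions this package
is built around:

1. **Measurement.** How do you turn a micro-CT volume of a tessellated
   shell into per-tile morphometrics (thickness, width, volume, in-plane
   area, neighbor count, local surface curvature)?
2. **Topology and statistics.** What do tile-shape (polygon-class)
   frequencies, Euler-type identities, and size distributions look like,
   and how do they change with scale?
3. **Growth rules.** Which local apposition rules can maintain a gap-free
   tiling on an expanding substrate — and which cannot?

Real volumes are large external datasets, so the package is organized
around *synthetic phantoms with full ground truth*: every stage of the
measurement pipeline can be validated against a phantom whose answer is
known by construction, and the growth model runs on generated
tessellations. The same functions apply unchanged to real volumes read
with `read_volume_tiff()`.

## Synthetic phantoms

`sample_hardcore_points()` scatters tessera growth centers by dart
throwing with a minimum pairwise spacing (a hard-core process): observed
tessellations are consistent with randomly placed centers subject to a
minimum nascent-tile size, and the hard-core radius is the knob that
emulates that minimum. `voronoi_tessellation()` equipartitions the surface
among the centers — planar diagrams via the Delaunay/Dirichlet machinery
of **deldir**, spherical diagrams cell-by-cell by clipping half-planes in
the gnomonic projection (great-circle bisectors project to straight
lines), with every vertex cross-verified against nearest-seed queries.
`goldberg_tessellation()` supplies the closed reference tilings (12
pentagons, all else hexagons) and `toroidal_hex_tessellation()` the
genus-1 counterexample.

`voxelize_shell()` then builds the image: each shell voxel belongs to its
nearest center unless it lies within half a gap width of a cell boundary
(implemented as `d2 - d1 < gap_width` for the two nearest centers, which
equals perpendicular distance `gap_width / 2` at the bisector). Spherical
lacunae — the voids left by cells engulfed during apposition — are carved
inside tiles at positions deep enough to stay fully enclosed. The
grayscale channel is a Gaussian-blurred, Gaussian-noised binary of the
labels. The voxel convention everywhere is 0-based indices with world
coordinate `(index + 0.5) * voxel`.

Phantom geometry mirrors the anatomy: a slab shell sits on a thin
unmineralized core with a larger free margin above (so "outward" is +z);
a spherical shell spans `[R - thickness, R]` with a generous outside
margin. `reference_phantom()` freezes the benchmark conditions used
throughout the tests: 1500 × 1500 µm slab, 100 µm shell, 5 µm voxels,
400 centers at ≥ 50 µm spacing, 10 µm gaps, two 7.5 µm lacunae per tile,
2 µm blur, noise at 10% of contrast.

What the phantom deliberately does *not* emulate: anatomical ridges and
fossae (curvature is varied only via plane/cylinder/sphere substrates),
mineral-density banding within tiles, scanner-specific intensity
calibration, and spatially correlated noise. Passing recovery tests
therefore demonstrates correctness of the algorithms under controlled
imaging physics, not robustness to every artifact of real scans.

## Segmentation

The pipeline is threshold → clean → distance transform → hierarchical
watershed:

* `threshold_volume()` keeps voxels at or above an explicit level. An
  Otsu suggestion (`otsu_level()`) is available but never applied
  silently.
* `clean_binary()` removes small foreground components (26-connectivity)
  and fills background voids fully enclosed by foreground
  (6-connectivity, size-capped) — the lacunar gaps. Background touching
  the volume border is never filled.
* `distance_map()` / `signed_distance_map()` are exact Euclidean distance
  transforms (separable lower-envelope algorithm, in C++). The distance
  transform is computed in 3D; for a thin shell this reduces to the
  in-plane behavior while remaining verifiable on phantoms.
* `watershed_instances()` grows basins from distance maxima in decreasing
  distance order. Two basins meeting at a saddle merge when
  `min(peak_a, peak_b) - saddle < persistence`; surviving basins keep
  voxels on a deterministic tie rule (smaller label id). A sensible
  persistence default is half the expected tile half-width — large enough
  to absorb within-tile distance maxima, far below between-tile depths.
  The suite checks this kernel against an exhaustive merge-tree oracle on
  small 2D images.

Proofreading is scriptable rather than interactive: `edit_labels()`
applies ordered `merge_edit()` / `split_edit()` operations (splits re-run
a marker-based watershed inside the label's support), and
`remove_partial_tesserae()` drops tiles below volume or thickness
thresholds. Every edit is logged in the volume's provenance log.

## Adjacency and morphometry

`build_rag()` connects labels with at least `min_contact` face-adjacent
voxel pairs; with `bridge_gap > 0` it also connects labels whose supports
come within that distance (synchronous label dilation), recovering
neighbors separated by unmineralized joints. A sensible bridge default is
the expected gap width plus one voxel. Face (6-)adjacency defines direct
contact; diagonal contacts are ignored as the conservative choice.

Per-tile measures follow the bounding-cuboid conventions:

* `outward_axis()` picks the cuboid face normal with the largest
  *length-normalized* sum of signed distances along the six axis rays
  from the tile center. Normalizing by ray length keeps a synthetic box
  volume from favoring directions with longer runs to the box face; ties
  break deterministically (+z, +y, +x, −z, −y, −x). The 6-axis
  quantization bounds the angular error at `acos(1/sqrt(3)) ≈ 54.7°`; in
  shells whose curvature radius is only a few tile widths, near-diagonal
  outward directions sit between nearly tied axes and the pick can flip —
  a documented limitation of the 6-direction rule.
* `tessera_thickness()` is the axis-aligned bounding-box side along that
  axis; `tessera_width()` the longest remaining side (so columnar tiles
  taller than wide are not misread); `tessera_volume()` the voxel count
  times voxel volume. Boxes are axis-aligned in the volume frame, so the
  thickness of strongly tilted tiles is overestimated — the cost of
  matching the cuboid convention rather than an oriented-box refinement.
* `plane_area()` reconstructs a tile's in-plane footprint from the RAG
  alone: neighbors ordered angularly in the fitted tangent plane,
  triangle-fan centroids projected onto the plane perpendicular to the
  fitted normal (the mean of fan-triangle normals; collinear degeneracies
  resolve by id order), shoelace area of the projected polygon. On a
  hexagonal lattice this returns exactly `sqrt(3)/2 s²`.
* `smooth_surface_from_rag()` triangulates the RAG (3-cliques = Delaunay
  triangles for Voronoi-derived graphs), subdivides once at edge
  midpoints and applies Taubin λ/µ smoothing — chosen over plain
  Laplacian smoothing because it preserves planes exactly and closed
  surfaces' scale. Defaults (20 iterations, λ = 0.5, µ = −0.6) are strong
  enough that curvature read off the mesh is not biased by the
  subdivision-level faceting at the coarse nodes while sphere radii stay
  within 5% of construction.
* `mesh_curvature()` fits a quadric over each vertex's 2-ring in the
  local normal frame and reports `K = k₁k₂`, `H = (k₁+k₂)/2`, averaged
  over a small neighborhood; the sign convention makes convex-outward
  surfaces (spheres) have `H > 0`. `tessera_curvature()` samples the
  field at the vertex nearest a tile center. Sphere, cylinder and plane
  phantoms recover their analytic curvatures in the tests.

`tessera_table()` assembles everything into one tibble per label volume —
the package's central tabular output — and `mineralized_fraction()`
reports labeled volume against the element mask.

## Tessellation statistics

`polygon_frequency()` tallies polygon classes (neighbor counts), dropping
boundary tiles by default since their degree undercounts their sides.
`euler_characteristic()` computes V − E + F on deduplicated vertices and
edges and *refuses open tessellations* rather than silently correcting
them — a nearly-but-not-fully covered surface is exactly the situation in
which the identity misleads. `hexagonal_deficiency()` returns
`Σ (6 − n)` over faces, which equals `6χ` for closed trivalent
tessellations (12 on the sphere, 0 on the torus) and
`#pentagons − #heptagons` when only 5/6/7-gons occur.

Size distributions are summarized by their peak: `peak_of_distribution()`
uses Freedman–Diaconis binning with parabolic refinement over the modal
bin (a fixed bin width can be supplied for strict reproducibility);
`rescale_distribution()` divides by the peak and histograms on a fixed
common grid; `self_similarity_distance()` is the L1 distance between
unit-area rescaled densities (0 identical, 2 disjoint). Peak scaling
across specimens is fit by `loglog_peak_regression()` — ordinary least
squares on log₁₀ scales, with reduced-major-axis deliberately *not* the
default — and each fit carries its isometric reference exponent from
dimensional analysis: lengths scale as area^0.5, areas as area^1, volumes
as area^1.5 against surface area. `neighbor_size_relation()` quantifies
the Lewis-law-like tendency of many-neighbored tiles to be larger.

## The growth model

`init_state()` turns a planar Voronoi tessellation into a growth state:
tile *i* is the intersection of half-planes, one per neighbor *j*, at
front offset `f_ij` from its center along the center-to-center direction,
clipped to the substrate box. The fiber between *i* and *j* carries gap
`g_ij = d_ij − f_ij − f_ji ≥ 0`; tiles start as Voronoi cells shrunk by
`sqrt(fill_fraction)`. This representation makes "apposition on a face" a
scalar update and makes overlap-freedom provable (fronts never advance
past half the remaining gap).

Each cycle, `expand_substrate()` scales centers and box by λ while the
rigid mineral keeps its fronts, so every gap opens by exactly
`(λ − 1) d_ij` — wider joints next to larger tiles, loading those fibers
more. Two apposition rules close gaps:

* `appose_constant(δ)`: every front advances `min(δ, g/2)`. Uniform
  tilings close exactly; heterogeneous tilings strand uncovered area next
  to their largest tiles, and `propose_new_tiles()` reports where new
  tiles would be forced in.
* `appose_proportional(k)`: every front advances `k·g/2` — the same on
  both ends of each fiber, because a stretched fiber pulls equally on
  both faces. Stated as a rule on tile size in the source hypothesis, the
  implemented primitive is *gap*-proportional; size-proportional total
  accretion then emerges (tested as a positive correlation between a
  tile's area and its per-cycle area increment). Coverage returns to 1,
  tile count and pattern are preserved, and rescaled area distributions
  are self-similar across cycles.

`voronoi_deviation()` measures the mean offset of each fiber's mid-gap
point from the center-to-center midpoint, `|f_ij − f_ji| / (2 d_ij)`.
Symmetric rules conserve the absolute front asymmetry while expansion
grows `d_ij`, so the deviation is nonincreasing: any starting
configuration drifts toward the Voronoi (equipartitioned) limit. Because
symmetric initialization is already at deviation 0, convergence is
exercised from deliberately asymmetric fronts (`perturb_fronts()`).
`chain_state()` provides a 1D reduction in which every behavior has a
closed form. Substrate expansion is isometric by default, matching the
observed shape-preserving growth; tile insertion is detection-only, since
insertion appears to play a minimal role in vivo. Out-of-plane (thickness)
growth is out of scope — thickness distributions hint at different rules
in that dimension.

## Numerical choices and problem sizes

Degenerate inputs fail loudly and specifically: infeasible hard-core
packings report the achieved count; unbounded or asymmetric spherical
Voronoi cells name the cell; open tessellations are refused by the
topology operations; all-foreground volumes are refused by the distance
transform. Determinism is part of every contract — fixed seeds give
byte-identical phantoms, and the watershed and proofreading operations
have explicit tie rules.

The suite's problem sizes are chosen so the full run takes a few minutes
on one core while still exercising each claim at meaningful scale: the
reference phantom is ~5 million voxels (segmented in seconds by the C++
kernels); topology identities run up to 5000-cell spherical tessellations;
growth separation uses 150–500-tile tilings over 10 cycles and 10 seeds;
degree and Lewis-law statistics use ~2600-cell tessellations (≥ 2000
interior). Known remaining limitations: adjacency below voxel resolution
(Voronoi edges shorter than one voxel) cannot be recovered from a label
volume; the 6-axis outward rule degrades at extreme shell curvature; and
axis-aligned bounding boxes overestimate thickness for tilted tiles.
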