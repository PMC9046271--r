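---
title: "Vascular network quantification with vascnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular network quantification with vascnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascnet)
```

## The problem

Pre-segmented vasculature volumes (light-sheet microscopy of cleared
brains, micro-CT of corrosion casts, fundus photographs) encode a vessel
network as a binary voxel mask. Quantitative questions -- how many
branchpoints, how long and how tortuous are the segments, how do radii
distribute -- require converting that mask into an annotated graph.
`vascnet` implements the full conversion: topology-preserving
skeletonization, radius estimation with a face-corrected distance
transform, 26-connectivity graph construction, automated removal of
spuriously labeled branchpoints, physical-length pruning, and segment- and
network-level morphometry, with optional atlas-ROI decomposition. All
computations work identically on 3D volumes and on 2D images (padded to a
single-slice volume, where the N26/N6 voxel neighborhoods reduce to N8/N4
pixel neighborhoods).

Conventions used throughout: arrays are indexed `(z, y, x)`, coordinates
are 0-based, and the per-axis physical resolution (µm or px per voxel) is
stored in the same `(z, y, x)` order. Anisotropic resolutions are
supported everywhere; distances are always computed in physical units.

## Skeletonization

Centerlines are extracted by six-subiteration directional parallel
thinning in the (26, 6) digital topology, the classical medial-axis
approach for binary volumes. In each subiteration, voxels exposed on one
of the six face directions are collected as deletion candidates if they
are *simple points*; candidates are then deleted sequentially with a
simplicity re-check, so every removal provably preserves connected
components, tunnels and cavities. A voxel is simple when (a) its
foreground 26-neighbors form exactly one 26-connected component and (b)
the background within its 18-neighborhood has exactly one 6-component
touching the voxel's faces. Voxels with exactly one foreground neighbor
are endpoints and never deleted, which keeps vessel termini in place. The
volume is zero-padded by one voxel before thinning and cropped after, so
border voxels need no special casing. Skeleton coordinates are emitted in
lexicographic `(z, y, x)` order, making vertex indexing deterministic.

The one behavior worth knowing about: a solid shape's skeleton ends
where the endpoint condition is first met, so tube phantoms rendered as
capsules retain their full axis, while shapes with flat or bulbous ends
can gain or lose roughly one voxel of centerline per end. The test suite
cross-checks the implementation against an independent reference
implementation of the same published algorithm on tube phantoms
(topology, Hausdorff distance, point counts).

## Radius estimation: the face-corrected distance transform

Classic EDT-based radius estimation measures from the centerline voxel
center to the *center* of the nearest background voxel. For a vessel one
voxel thick at 1 µm resolution this reports a 1 µm radius -- double the
putative 0.5 µm -- because the true vessel boundary runs through the
*face* between foreground and background. The corrected ("modified") EDT
measures to the face for background voxels reachable by pure axis-aligned
steps:

* absolute delta with exactly one nonzero component `d` along an axis of
  resolution `r`: distance `d*r - r/2`;
* every other delta (diagonal in any way): plain Euclidean
  `sqrt(sum((d_i * r_i)^2))`, uncorrected.

So a delta of `(0, 0, 5)` at unit resolution gives 4.5, while `(1, 1, 1)`
stays `sqrt(3)`. Corrected distances are precomputed into a lookup table
indexed by the absolute delta triple (`build_medt_lut()`); deltas beyond
the table are computed on the fly by the same rule.

Per centerline point, a box expands in Chebyshev shells until at least
four background voxels are found, then one further safety shell, and the
radius is the mean of the four smallest corrected distances. Averaging
four values absorbs small surface divots and imaging artifacts. Two
numerical details:

* **Stopping rule.** Under anisotropy (and, for shells beyond radius ~3,
  even isotropically) a physically nearer background voxel can live in a
  later Chebyshev shell than the four already found. After the safety
  shell, expansion therefore continues while the fourth-smallest distance
  still exceeds the smallest distance the next shell could possibly
  contain (`min_a((s+1) r_a - r_a/2)`). This makes the search provably
  equivalent to brute force over all background voxels -- an equivalence
  the test suite asserts exactly on random phantoms, isotropic and
  anisotropic.
* **Degenerate volumes.** If the whole volume holds fewer than four
  background voxels, all available distances are averaged and a warning
  is emitted; a volume with no background yields `NA`.

The mEDT radius is never larger than the uncorrected EDT radius
(corrections only shrink axial distances), and never smaller than half
the finest axis resolution.

## Graph construction

Each skeleton point becomes a vertex carrying its coordinate and radius.
Edges come from scanning, for every point, the 13-offset half of the
26-neighborhood oriented towards `(z_max, y_max, x_max)`; since exactly
one of every antipodal offset pair is scanned, each neighbor pair is
visited once and parallel edges or self-loops cannot arise. A spatial
hash (linearized coordinate keys) makes construction linear in the number
of points. The test suite checks the resulting edge set against a
brute-force all-pairs 26-adjacency oracle.

Degree classifies vertices: endpoints (degree <= 1), path vertices
(degree 2), branchpoints (degree > 2).

## Spurious branchpoint filtering

Under 26-connectivity, several vertices at one junction can all reach
degree > 2, forming small all-to-all connected cliques (and clusters of
cliques at segmentation or filling artifacts), which inflates branchpoint
counts. `filter_cliques()` removes them in two passes.

**Pass 1 (class 1).** Maximal cliques of three or four vertices among
branchpoint candidates are weighted: `weight(v) = radius(v) + mean(radius
of v's neighbors outside the clique)` (vertices without outside neighbors
keep their own radius). Higher weight marks proximity to the parent,
larger-vessel side of the junction. The edge between the two
lowest-weighted members is removed -- eliminating 3-cliques outright and
simplifying 4-cliques -- and the pass repeats (up to 5 sweeps) because
removals can expose new cliques. Ties are broken towards the lowest
vertex indices for determinism. Removing one edge of a clique can never
split a component.

**Pass 2 (classes 2 and 3).** Remaining clique clusters (connected groups
of clique vertices) are collapsed. Clusters of fewer than 50 vertices
(class 2) become a single vertex carrying the cluster's mean radius at
its voxel-rounded centroid, wired to every external projection target;
clusters of 50 or more (class 3) are scanned by a sliding window (default
10 voxels, configurable) along their longest bounding-box axis, each
window collapsing by the class-2 rule with consecutive window vertices
chained. The window length is a free parameter of the method; 10 voxels
keeps the replacement path at roughly the scale of the junction geometry
that produced the cluster. The two passes alternate until no maximal
clique of size >= 3 remains among branchpoint candidates.

Invariants maintained (and property-tested on random phantoms): connected
component count is unchanged, branchpoint count never increases, merged
radii stay within the cluster's radius range.

## Pruning

Two physically parameterized filters clean the graph, mirroring removals
into a copy of the volume: *isolated segments* (components containing no
branchpoint) shorter than the isolated filter length are deleted, and
*endpoint segments* (bounded by one endpoint and one branchpoint) shorter
than the endpoint prune length are deleted with the branchpoint retained
and reclassified by its new degree. Defaults are 10 and 5 physical units.
Pruning decisions use chained voxel-to-voxel edge lengths, include the
connecting edge to the boundary branchpoint, and run in a single
(non-recursive) pass, so real vessels are not progressively eroded.
Vertices on branchpoint-to-branchpoint paths can never be pruned, and
larger thresholds never retain more vertices.

## Segments and features

Removing branchpoints from the final graph leaves path components; each
is one vessel segment, ordered end to end, with adjoining branchpoints
recorded and their coordinates appended to the path (otherwise
inter-junction lengths are systematically short). Cycle components are
closed explicitly so their zero chord marks tortuosity as undefined;
such segments are excluded from tortuosity means and counted.

**Length.** Voxel centerlines carry half-voxel staircase jitter; summing
voxel-to-voxel edges overestimates length (measurably by 1-8% depending
on orientation), and an interpolating spline through every voxel inherits
most of that bias. Segment length is therefore measured along a clamped
cubic B-spline (Cox-de Boor basis): paths of up to 6 vertices use their
coordinates directly as control points of a degree `min(3, n-1)` spline;
longer paths are fitted by least-squares B-spline approximation under
chord-length parameterization with one control point per 3 path vertices
and the curve clamped to the exact path endpoints, which runs the curve
through the middle of the staircase. The curve is sampled at `k = max(2,
2n)` points and the polyline length returned. On phantoms this recovers
straight-tube lengths exactly and a 20-voxel-radius semicircle to within
about 1%, the residual being genuine centerline extension into the
capsule end caps rather than spline error.

**Tortuosity** is the arc-chord ratio: spline length divided by the
Euclidean distance between the segment's first and last path coordinates.
It is >= 1 up to spline tolerance (1e-6) for all defined segments.

**Radius statistics** (mean, min, max, sd) use interior path vertices
only -- appended branchpoint radii reflect junctions, not the segment.
**Lateral surface area** and **volume** are the cylinder identities
`2*pi*r_mean*L` and `pi*r_mean^2*L`.

Network-level reports aggregate counts (branchpoints = degree > 2,
endpoints = degree 1 on the final graph), totals, *segment partitioning*
(segment count divided by total network length; 0 when the network is
empty), the vascular area/volume fraction, and per-radius-bin segment
counts with mean features. Default bins are unit-width in the dataset's
physical units with the top bin catching larger radii; edges are
configurable. Bin counts always sum to the segment count.

The reduced (branchpoint-level) graph exports one edge per segment with
its features, and serializes the full segment path into a string edge
attribute, since most graph formats do not allow array attributes.

## Annotated (ROI) analysis

An annotation volume (integer atlas IDs, or RGB triples matched exactly)
plus a named ROI specification decomposes the analysis: ROIs are
processed in bins of at most 254 regions, each bin casting labels 1-255
onto the vasculature in one pass (0 is background), with the labeled
array cached to disk as a flat binary file. Each ROI's vasculature is
analyzed by the full pipeline independently and the per-ROI graphs are
merged as a disjoint union with global coordinates preserved. Segmenting
*before* skeletonization is a deliberate trade: it bounds memory and
time, at the cost that vessels crossing an ROI boundary are split there,
creating an endpoint on each side; boundary-heavy ROIs therefore
over-count endpoints and under-count through-going length.

## The phantom generator

`phantom_spec()` / `render_phantom()` create binary volumes with exact
analytic ground truth: capsule tubes (a voxel is foreground iff its
center lies within the tube radius of the start-end segment), in-plane
circular arcs, and Y-bifurcations, plus optional seeded surface divots
and hole punching to probe robustness. Ground truth records branchpoint
and endpoint counts and per-primitive analytic length and tortuosity.
Rendering is deterministic given the seed.

Phantoms emulate the *geometry* the pipeline must recover -- junctions,
curvature, anisotropic sampling, small-vessel thinness -- under perfect
segmentation. They deliberately do not emulate segmentation noise,
intensity artifacts, contact between unrelated vessels, or
physiologically realistic branching hierarchies; passing phantom tests
therefore validates the reconstruction machinery, not robustness to
upstream segmentation quality, which remains the user's responsibility.

Two randomized generators drive the junction benchmark:
`phantom_bifurcation()` (trunk plus two arms tilted 30-60 degrees to
opposite sides in one plane, radii 2-3 voxels, ground truth one
branchpoint) and `phantom_crossing()` (two tubes through a common point
at 50-90 degrees, ground truth one junction). The benchmark suite uses a
90/10 bifurcation/crossing mix: bifurcations are the canonical junction
of real vascular trees, while crossings are the known-hard minority case
-- two finite-radius tubes crossing genuinely produce two nearby
medial-axis junctions in most orientations, so crossings may legitimately
resolve to one more branchpoint than their curve-space ground truth.
`benchmark_branchpoints()` reproduces the external-benchmark protocol:
ground truth is counted by skeletonizing a branchpoint sphere label
volume and counting connected components.

## Problem sizes and runtimes

The shipped tests use phantoms of 24-69 voxels per axis (seconds per
volume on one core); the junction benchmark runs 50 phantoms at 64^3, and
oracle-equivalence checks run brute-force comparisons on volumes up to
32^3, where exhaustive enumeration is still cheap. All stages scale
linearly in foreground voxel count except clique detection, which is
restricted to the (small) subgraph of branchpoint candidates precisely to
keep it tractable on large volumes.

## Known limitations

* Input must be pre-segmented; no thresholding, denoising or
  anisotropy-correcting smoothing is applied.
* NIfTI affine/orientation metadata is ignored; the user-supplied
  resolution is authoritative.
* JPEG/BMP 2D inputs are not read (no reader in the R dependency stack);
  convert to PNG or TIFF.
* ROI boundary effects as described above.
* The graph is undirected; artery/vein hierarchy and flow direction are
  out of scope.
* Radius estimation assumes the background truly abuts the vessel wall;
  for vessel-filled preparations with interior voids, four-lowest
  averaging mitigates but does not remove bias.

## A minimal session

```{r example, eval = FALSE}
ph <- phantom_bifurcation(seed = 1)
ana <- run_analysis(ph$volume, filter_length = 10, prune_length = 5)
ana$report$network
ana$segments
export_graph(ana$reduced, "network.graphml")
```
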