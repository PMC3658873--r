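---
title: "Methods: tile-pyramid maps for biological data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-pyramid maps for biological data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomaps)
```

# The model

A pan-and-zoom map widget consumes a *tile pyramid*: zoom level $z$ is a
$2^z \times 2^z$ grid of fixed-size tiles (default 256 px) jointly
depicting one scene, stored as `{z}/{x}/{y}.png`. The zoom-$z$ raster is
$256 \cdot 2^z$ pixels on a side and a pyramid with levels $0..z_{max}$
holds $\sum_{i=0}^{z_{max}} 4^i$ tiles — the count quadruples per level,
which is why `tile_pyramid()` caps $z_{max}$ at 8 by default (87,381
files; deeper pyramids are infeasible to distribute and need an explicit
`z_cap` override).

genomaps renders biological scenes into this structure *offline*, once,
so that all interactivity left to the client is panning, zooming, and
reading small pre-exported JSON files. The package's job is therefore
two-fold: (1) compute layouts that make zooming a meaningful data query
(semantic zoom), and (2) emit pixel-exact tiles plus the manifests that
make elements selectable without a server.

## Coordinates and rendering

Everything lives in normalized world coordinates $[0,1)^2$, origin
top-left, $y$ downward, half-open intervals — matching raster
conventions and avoiding double-counted boundaries. `point_to_tile()` is
`floor(n * 2^z)` per axis with the fractional remainder as the in-tile
pixel offset.

Scenes are lists of vector primitives (rectangles, discs, segments,
polylines, cell grids, radial glows), optionally generated per zoom
level. Rasterization is *pixel-center sampled*: a pixel's color is a pure
function of its global pixel index and the primitive list, never of the
viewport it is rendered through. This gives the mosaic property — tiles
assembled at any zoom equal the monolithic render bit for bit — by
construction, and it is what makes background-tile deduplication safe.
In-memory renders are snapped to the 8-bit grid PNG files use
(`round(v * 255) / 255`), so comparisons against tiles read back from
disk are exact.

Deduplication (`deduplicate_tiles`) deletes every tile pixel-identical to
the pure background tile, stores one shared copy as `background.png`
*outside* the slot tree, and exports the covered addresses; every slot is
then either a unique file on disk or a listed address, and
`reconstruct_tiles()` restores the original pyramid exactly. Equality is
exact by default; a tolerance is configurable but pointless for the
lossless PNG path, which is also why only PNG is supported — lossy
encodings would break the pixel-equality invariant dedup relies on.

Text is deliberately never rasterized into tiles: gene names, axis labels
and node names are exported in manifests for client-side drawing, which
keeps labels crisp at every zoom and keeps the renderer free of font
dependencies.

# Semantic zoom for co-expression maps

Gene similarity is the correlation distance $1 - r$ (Pearson), because
co-regulation is about profile shape, not magnitude; Euclidean distance
is available by argument for magnitude-sensitive uses. Constant profiles
have no defined correlation and are rejected with the offending genes
named (the heatmap orderer falls back to Euclidean in that case).

`build_dendrogram()` is average-linkage agglomeration (via
`stats::hclust`) — a robust default when no particular linkage is
dictated by the data. `cuts_for_zoom()` assigns one cut per zoom: the
coarsest zoom cuts at the root height (one cluster), and cut heights then
decrease geometrically to a low quantile (default 5%) of the merge
heights. Geometric spacing matches how zooming works — each level doubles
the magnification, so each level should roughly halve the dissimilarity
scale in view. Cutting one tree at decreasing heights makes the
partitions nested and the cluster counts monotone by construction.

The embedding places *cluster centers* by classical MDS (`cmdscale`) of
inter-centroid correlation distances, then arranges each cluster's genes
on a deterministic sunflower spiral inside a disc whose area is
proportional to membership (total disc area about 30% of the world).
Discs of distinct clusters are made disjoint by an iterative, seedless
pairwise repulsion pass in cluster-id order (cap 200 iterations). MDS has
a reflection ambiguity; it is fixed by requiring the largest cluster's
center left of the second largest, so layouts are reproducible. If all
centroids coincide (a degenerate but reachable input), centers fall back
to uniform angular placement with a warning. This construction is a
deliberately simple planar embedding with discrete cluster structure; it
does not claim equivalence to any particular published embedding
algorithm.

Cluster boundaries are convex hulls of member positions padded outward by
a fixed world margin — visible group outlines without the complexity of
concave hulls, accepting that a convex outline can overstate a cluster's
footprint.

# Heatmaps

Rows and columns are ordered by dendrogram leaf order on the same
correlation distance (columns by clustering the transposed matrix);
`--no-cluster` preserves curated input order. The heatmap fills the whole
world square — cell $(i,j)$ covers
$[(j{-}1)/n_c, j/n_c) \times [(i{-}1)/n_r, i/n_r)$ — so `cell_at()` is
exact integer arithmetic and axis-label pixel coordinates double per zoom
level exactly, which is the invariant a client needs to keep labels
synchronized while panning. Cell borders draw only when a cell is at
least 4 px wide on screen. The colormap is a blue–yellow–red diverging
ramp centered on the matrix median (piecewise-linear on each side), with
out-of-range values clamped once with a warning; subset glyphs reuse the
full matrix's scale so colors are comparable across views.

# Genome browser

Chromosomes stack vertically in natural order (1, 2, …, 10, …, X, Y, MT),
each an equal-height band; base pair to $x$ is linear with a scale shared
across chromosomes (the longest spans the full width), so no coordinate
distortion is introduced anywhere. A gene's anchor is the linear image of
its interval midpoint. Coordinates are 0-based half-open internally
(BED's convention; GFF3 is shifted on ingest via `rtracklayer`).

**Glyph spreading.** At the deepest zoom each glyph must be at least
`min_width` px wide (default 8). Widths are widened to that minimum and
centers $x_i$ solve

$$\min \sum_i (x_i - a_i)^2 \quad \text{s.t.} \quad
x_{i+1} - x_i \ge \tfrac{w_i + w_{i+1}}{2},$$

i.e. minimal total displacement subject to order-preserving
non-overlap. Substituting the cumulative spacing reduces this to
unweighted isotonic regression, solved exactly by the
pool-adjacent-violators sweep; the test suite cross-checks against
`stats::isoreg` as an independent oracle. Results are clamped into the
chromosome band; both walls are monotone so clamping preserves spacing
(the clamp can in principle trade optimality for feasibility near a wall,
never correctness). If the total required width exceeds the band, the
error names the chromosome and the smallest $z_{max}$ that would fit —
multi-row stacking is a possible extension but v1 refuses rather than
guessing a vertical layout. Displaced glyphs keep a leader line to their
true anchor; an undisplaced glyph's leader has zero length.

Highlight markers are radial alpha icons,
$\alpha(d) = \text{peak} \cdot \max(0, 1 - d/\text{radius})$, composited
source-over so $k$ co-located markers reach
$1 - (1-\text{peak})^k$ — monotonically amplifying and saturating below
1, which makes dense highlighted regions stand out at overview zooms.
Per-gene glyph identity is preserved at every zoom; expression is never
aggregated over genomic windows, because variability among co-located
genes would make such aggregates misleading.

# Interaction networks

Relevance is intrinsic importance (a supplied weight, else degree)
blended with one diffusion round,
$r_i = (1-\alpha) b_i + \alpha \,\overline{b}_{N(i)}$ (isolated nodes
keep $b_i$), min–max normalized; $\alpha = 0.3$ by default — a mild
diffusion that lets a well-connected neighborhood lift a node without
drowning its own signal. One round is the simplest combination that is
both "intrinsic" and "diffused"; iterated diffusion converges toward an
eigenvector-like score that erases the intrinsic part, which is not the
intent.

Zoom strata show the top $2^{-(z_{max}-z)}$ fraction of nodes by score
quantile, ties kept, everything visible at $z_{max}$ — nested by
construction. Five zoom levels is the default.

The base layout is Fruchterman–Reingold (`igraph::layout_with_fr`) under
a fixed seed. For any edge longer than `d_max` (default 0.15 world
units), the *lower*-relevance endpoint is copied next to the higher one —
hubs stay put, as cities do on maps — on a collision-avoiding ring at
radius $\le d_{max}/2$ (16 angles at two radii; failure to place is an
error suggesting a larger `d_max`). Every original edge then has exactly
one realization with endpoint copies within `d_max`, which is asserted as
a hard post-condition. An edge is drawn at the first zoom where both its
canonical endpoints are visible; whether an edge between two
high-relevance nodes should appear before both are visible is a genuinely
open semantic choice, and v1 requires both. The copy registry and
per-copy interactor lists are exported so a client can implement the
jump-to-copy list.

# Tract maps

Curve dissimilarity is the symmetrized mean closest-point distance — the
standard streamline measure: mean over points of one curve of the
distance to the nearest point of the other, averaged both ways. It is
symmetric and zero exactly for coinciding point sets (it ignores
traversal direction, which is appropriate for tracts). Clustering is
average-linkage on this distance with a caller-chosen $k$ (tract atlases
are curated; no model selection is attempted), and each cluster's
centroid is the member minimizing summed distance to co-members —
verified exhaustively in tests. Projections drop one axis per anatomical
plane (x = left-right, dropped by sagittal; y = posterior-anterior,
coronal; z = inferior-superior, transverse), so the three planes jointly
preserve every coordinate. Members are linked from the centroid's
endpoints to their own projected endpoints by thin lines; per-cluster
statistics (count, mean length, mean centroid distance) go into detail
records.

# Hit grids and selection

Selectable geometry is split over a $G \times G$ grid (default 10), an
element listed in every cell its bounding box intersects — conservative
and cheap, and safe because `hit_test()` re-checks exact distances
(point-to-polyline as minimum over segments, not vertex-only). A click
loads only the cells within the tolerance (default 0.01 world units, a
configurable stand-in for "a few pixels") of the click point, which
bounds file accesses by $(\lceil 2\,\text{tol}\,G\rceil + 1)^2$;
the candidate set provably contains every element within tolerance, so
the result equals brute force, ties broken by id. Rectangle selection
uses *enclosure* (users draw rectangles around what they want), with
intersection semantics behind a flag.

# Synthetic data

The generators emulate the qualitative structure each viewer exists for,
with ground-truth labels:

* `synth_expression`: per-cluster random template profiles (standard
  normal, so distinct clusters are near-orthogonal in shape) plus member
  noise of `noise_sd = 0.1` by default against unit-scale templates —
  clearly separated but not trivial. Flagship size 300 genes x 24
  conditions, 3 clusters.
* `synth_graph`: Barabási–Albert preferential attachment ($m$ seed nodes
  without edges, each newcomer attaching to $m$ distinct
  degree-proportional targets), giving exactly $m(n-m)$ edges, a
  connected simple graph and heavy-tailed degrees.
* `synth_genome`: per chromosome, one dense interval holding a chosen
  fraction of the genes in 10% of the span, the rest near-uniform;
  non-overlapping by construction (evenly spaced slots with jitter).
* `synth_tracts`: bundle templates are cubic splines through random
  control points at well-separated origins; members add a rigid offset
  and per-point jitter of scale `spread`.

What passing tests on these fixtures shows — and does not show: recovery
of planted, well-separated structure demonstrates the pipeline's
correctness (distances, linkage, cuts, clustering are wired right), not
that real expression compendia or interactomes will yield clusterings of
any particular quality; real data have correlated noise, batch structure
and scale-mixtures the generators deliberately omit.

# Determinism and numerical choices

Every stochastic step flows through an explicit seed (recorded in
`build.json` and in fixture sidecars); repulsion and spreading passes are
seedless and order-deterministic; renders are pixel-pure; the build log
contains no timestamps. Hence the contract checked end-to-end in the
tests: identical config plus fixture seed yields byte-identical site
directories for every viewer.

Test and verification problem sizes (pyramids at $z_{max} = 2$, fixtures
of 60–300 genes, 80–300 nodes, 60 tracts, 20 replicate seeds for
stochastic properties) were chosen so the full suite completes in a few
minutes while still exercising every contract at non-toy scale; the
closed-form pyramid arithmetic is checked at full scale ($z_{max} = 8$)
since it costs nothing.

Known limitations: no on-the-fly serving or HTTP; no re-projection of
geographic coordinate systems; heatmaps zoom both axes together; genome
spreading refuses rather than stacks when a band overflows; network
rendering draws no edge bundling; tract selection is restricted to
pre-computed clusters. The static `viewer.html` is a passive asset
generated from a template — wiring a concrete map widget to the tiles is
left to the deployment.
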