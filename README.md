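# genomaps

Pre-rendered, tile-based dissemination of biological data.

Modern pan-and-zoom map widgets (Leaflet, OpenLayers, the Google Maps
`ImageMapType`) consume a very simple artifact: a directory of fixed-size
image tiles laid out as `{z}/{x}/{y}.png`, where zoom level *z* is a
2^z x 2^z grid jointly depicting one scene. **genomaps** renders four
common kinds of biological data into exactly that artifact — plus the JSON
manifests a client needs for selection, search and details-on-demand — so
that a fully analyzable, multi-scale view can be published by copying a
directory onto any web server. No database, no rendering service, no
server-side computation at view time.

It is aimed at bioinformaticians who want to hand collaborators a
browsable view of a dataset (an expression compendium, an interactome, a
genome-wide expression track, a tractography atlas) without asking them to
install anything.

## What it computes

* **Tile pyramids** (`tile_pyramid`, `render_pyramid`): a zoom-`z` raster
  is `tile_size * 2^z` pixels on a side; a pyramid with levels `0..z_max`
  holds `sum(4^(0:z_max))` tiles (87,381 files for nine zoom levels at
  tile size 256, i.e. a 65,536-pixel raster). Background-only tiles are
  deduplicated into a single shared tile plus an address manifest
  (`deduplicate_tiles`), and the pyramid is exactly reconstructable.
* **Co-expression maps** (`build_coexpr`): genes are placed in the plane
  by expression similarity (correlation distance `1 - r`, average-linkage
  clustering, classical MDS of cluster centroids), with *semantic zoom*:
  a hierarchical clustering is cut at a height linked to the zoom level,
  so groups become smaller and tighter as you zoom in; each group draws a
  bounding curve and a mean-expression glyph.
* **Clustered heatmaps** (`build_heatmap`): rows and columns ordered by
  dendrogram leaf order, tiles plus zoom-synchronized axis-label
  manifests and an exact coordinate-to-cell lookup (`cell_at`).
* **Genome browsers** (`build_genome`): chromosomes stacked vertically on
  a shared linear base-pair scale (no distortion); in dense regions,
  glyphs are widened to a minimum legible width and de-overlapped by an
  exact order-preserving minimal-displacement pass
  (pool-adjacent-violators), each displaced glyph keeping a leader line
  to its true genomic anchor; additive alpha highlight markers make dense
  hit regions glow at overview zooms.
* **Interaction networks** (`build_network`): node relevance is intrinsic
  importance blended with one round of neighborhood diffusion,
  `r_i = (1 - alpha) b_i + alpha mean(b_j : j ~ i)`; overview zooms show
  only high-relevance nodes (nested strata, everything visible at
  `z_max`); *vertex splitting* duplicates the lower-relevance endpoint of
  any edge drawn longer than `d_max`, so every interaction is locally
  visible, with a copy registry exported for the client's copies list.
* **Tract maps** (`build_tracts`): 3D curves clustered by the
  symmetrized mean closest-point distance, centroid tracts selected per
  cluster, projected onto the sagittal/coronal/transverse planes, with
  per-cluster statistics in detail records.
* **Hit grids** (`build_grid`, `hit_test`, `rect_select`): selectable
  geometry split over a 10 x 10 spatial grid into per-cell JSON files, so
  a client fetches only the clicked cell; the reference hit test is
  provably identical to brute force.

All synthetic inputs (planted expression clusters, preferential-attachment
graphs, density-alternating genomes, tract bundles) come from the
package's own seeded generators (`synth_*`, `make_fixtures`), which also
power the test suite.

## Worked example

```r
library(genomaps)

# a planted 3-cluster expression matrix, 90 genes x 12 conditions
fx <- synth_expression(n_genes = 90, n_conditions = 12, n_clusters = 3,
                       noise_sd = 0.1, seed = 7)
tsv <- tempfile(fileext = ".tsv")
write_expression_tsv(fx$matrix, tsv)

site <- tempfile("coexpr_site")
cfg <- build_config("coexpr", list(matrix = tsv), site, z_max = 3, seed = 7)
build_site(cfg)
#> building coexpr site at /tmp/...coexpr_site...
#> rendered 85 tiles into /tmp/...coexpr_site.../tiles
#> deduplicated 31 background tiles
#> exported hit grid (G=10) for 90 selectable elements
#> wrote 85 tiles total; build complete
```

The 85 tiles are `sum(4^(0:3))` — the closed form behind the pyramid —
and 31 of them showed nothing but background, so they were replaced by one
shared `background.png` plus address list. The site directory now holds
`tiles/`, `manifests/` (gene positions, per-zoom cluster membership,
cluster mean profiles, a searchable gene index), `grid/` (hit-test cells),
`details/` (per-gene records), `viewer.html`, and `build.json`; rebuilding
from that recorded config reproduces every file byte for byte.

Interrogating the result from R works the same way a client would:

```r
cuts <- build_coexpr(fx$matrix, 0, 3)$cuts
vapply(cuts, function(cc) length(unique(cc$partition)), integer(1))
#> [1]  1  3  9 85     # cluster count grows as the cut height drops with zoom
mclust::adjustedRandIndex(cuts[[2]]$partition, fx$labels)
#> [1] 1               # the zoom-1 cut recovers the planted clusters exactly
```

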