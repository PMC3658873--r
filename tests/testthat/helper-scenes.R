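# Shared fixture scenes and small utilities for the suite.

uniform_scene <- function(background = "white") {
  scene(list(), background = background)
}

quadrant_scene <- function() {
  scene(list(prim_rect(0, 0, 0.5, 0.5, "firebrick")), background = "white")
}

dense_heatmap_scene <- function(nr = 40, nc = 12, seed = 5) {
  m <- with_test_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  prim <- prim_cellgrid(0, 0, 1, 1, expression_colormap(m))
  scene(list(prim), background = "white")
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Adjusted Rand index between two labelings (wraps the reference
# implementation in mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

tile_path_for_test <- function(dir, z, x, y) {
  file.path(dir, z, x, paste0(y, ".png"))
}

# Count image files in a tile directory (excludes the shared background tile).
n_slot_files <- function(dir) {
  length(list.files(dir, pattern = "^[0-9]+\\.png$", recursive = TRUE))
}
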