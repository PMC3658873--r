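## Clustered expression heatmap rendered as a tile pyramid, with
## zoom-synchronized axis-label manifests and coordinate -> cell lookup.

#' Diverging expression colormap
#'
#' Maps expression values to a blue-yellow-red diverging colormap centered
#' on the median (of `range_from`, so glyphs for subsets can share the full
#' matrix's scale). Values outside the reference range are clamped with a
#' single warning.
#'
#' @param values Numeric matrix of expression values.
#' @param range_from Numeric data defining min/median/max of the scale
#'   (default: `values` itself).
#' @return Array `nrow(values) x ncol(values) x 3` of RGB in `[0, 1]`.
#' @export
expression_colormap <- function(values, range_from = values) {
  lo <- min(range_from); hi <- max(range_from); md <- stats::median(range_from)
  v <- values
  if (any(v < lo | v > hi)) {
    warning("expression values outside colormap domain were clamped")
    v <- pmin(hi, pmax(lo, v))
  }
  # piecewise-linear map: lo -> 0, median -> 0.5, hi -> 1
  u <- ifelse(v <= md,
              if (md > lo) 0.5 * (v - lo) / (md - lo) else 0.5,
              if (hi > md) 0.5 + 0.5 * (v - md) / (hi - md) else 0.5)
  if (lo == hi) u[] <- 0.5
  ramp <- grDevices::colorRamp(c("#313695", "#FFFFBF", "#A50026"))
  rgb <- ramp(as.numeric(u)) / 255
  array(rgb, dim = c(nrow(values), ncol(values), 3))
}

#' Order a matrix for heatmap display
#'
#' Rows and columns are arranged to place co-regulated genes and
#' conditions together: both axes are ordered by the dendrogram leaf order
#' of average-linkage clustering on the co-expression distance
#' ([build_dendrogram]). Falls back to Euclidean distance when profiles on
#' an axis are constant (correlation undefined), and to the identity order
#' for single-row/-column matrices or when `cluster = FALSE`.
#'
#' @param m Expression matrix.
#' @param cluster Cluster at all, or preserve input order (curated input)?
#' @return An object of class `gm_heatmap_layout`: list with `row_order`,
#'   `col_order` (integer permutations), `gene_ids`, `condition_ids` in
#'   display order. Cells tile the full world square: cell (i, j) in
#'   display order covers `[(j-1)/nc, j/nc) x [(i-1)/nr, i/nr)`.
#' @export
order_matrix <- function(m, cluster = TRUE) {
  stopifnot(nrow(m) >= 1, ncol(m) >= 1)
  axis_order <- function(x) {
    if (nrow(x) < 2 || !cluster) return(seq_len(nrow(x)))
    tree <- tryCatch(build_dendrogram(x),
                     error = function(e) build_dendrogram(x, "euclidean"))
    tree$order
  }
  ro <- axis_order(m)
  co <- axis_order(t(m))
  structure(list(row_order = ro, col_order = co,
                 gene_ids = rownames(m)[ro], condition_ids = colnames(m)[co],
                 n_rows = nrow(m), n_cols = ncol(m)),
            class = "gm_heatmap_layout")
}

#' World rectangle of a heatmap cell
#'
#' @param layout A `gm_heatmap_layout`.
#' @param i,j Display row and column (1-based).
#' @return Numeric `c(x0, y0, x1, y1)` in world coordinates.
#' @export
cell_rect <- function(layout, i, j) {
  c((j - 1) / layout$n_cols, (i - 1) / layout$n_rows,
    j / layout$n_cols, i / layout$n_rows)
}

#' Look up the heatmap cell under a world coordinate
#'
#' The inverse of [cell_rect()] under the half-open convention; used by
#' clients to implement mouse-over gene/condition readouts.
#'
#' @param nx,ny World coordinates.
#' @param layout A `gm_heatmap_layout`.
#' @return List with `gene_id`, `condition_id`, `row`, `col` (display
#'   indices), or `NULL` if the point is outside the heatmap extent.
#' @export
cell_at <- function(nx, ny, layout) {
  if (nx < 0 || nx >= 1 || ny < 0 || ny >= 1) return(NULL)
  j <- floor(nx * layout$n_cols) + 1L
  i <- floor(ny * layout$n_rows) + 1L
  list(gene_id = layout$gene_ids[i], condition_id = layout$condition_ids[j],
       row = i, col = j)
}

#' Heatmap scene
#'
#' One cell-grid primitive covering the world square, ordered per the
#' layout; cell borders appear only at zooms where cells are at least 4
#' pixels wide.
#'
#' @param m Expression matrix.
#' @param layout A `gm_heatmap_layout` for `m`.
#' @param colormap Colormap function (default [expression_colormap()]).
#' @param background Background color.
#' @return A [scene()].
#' @export
heatmap_scene <- function(m, layout, colormap = expression_colormap,
                          background = "white") {
  stopifnot(layout$n_rows == nrow(m), layout$n_cols == ncol(m))
  ordered <- m[layout$row_order, layout$col_order, drop = FALSE]
  cols <- colormap(ordered)
  scene(list(prim_cellgrid(0, 0, 1, 1, cols, border_min_px = 4)),
        background = background)
}

#' Zoom-synchronized axis-label manifest
#'
#' For each zoom level, the pixel coordinate of every gene label (y axis)
#' and condition label (x axis), at the center of the label's cell. A
#' client pans/zooms these with the map; coordinates exactly double from
#' one zoom to the next.
#'
#' @param layout A `gm_heatmap_layout`.
#' @param z_min,z_max Zoom range.
#' @param tile_size Tile edge in pixels.
#' @return List keyed by zoom (as character), each a data.frame with
#'   `label`, `axis` (`"x"`/`"y"`), `px` (pixel coordinate along the axis).
#' @export
axis_manifest <- function(layout, z_min, z_max, tile_size = 256) {
  stopifnot(z_min <= z_max)
  out <- list()
  for (z in z_min:z_max) {
    side <- tile_size * 2^z
    ypx <- ((seq_len(layout$n_rows) - 0.5) / layout$n_rows) * side
    xpx <- ((seq_len(layout$n_cols) - 0.5) / layout$n_cols) * side
    out[[as.character(z)]] <- data.frame(
      label = c(layout$gene_ids, layout$condition_ids),
      axis = c(rep("y", layout$n_rows), rep("x", layout$n_cols)),
      px = c(ypx, xpx),
      stringsAsFactors = FALSE)
  }
  out
}

#' Build all heatmap artifacts
#'
#' @param m Expression matrix.
#' @param z_min,z_max Zoom range.
#' @param cluster Cluster rows/columns (see [order_matrix()])?
#' @param tile_size Tile edge in pixels.
#' @return List with `layout`, `scene`, `manifests` (axis labels plus the
#'   cell-lookup manifest: display orders and extent, enabling client-side
#'   [cell_at()]).
#' @export
build_heatmap <- function(m, z_min = 0, z_max = 4, cluster = TRUE,
                          tile_size = 256) {
  layout <- order_matrix(m, cluster = cluster)
  sc <- heatmap_scene(m, layout)
  manifests <- list(
    axis_labels = axis_manifest(layout, z_min, z_max, tile_size),
    cell_lookup = list(gene_ids = layout$gene_ids,
                       condition_ids = layout$condition_ids,
                       n_rows = layout$n_rows, n_cols = layout$n_cols))
  list(layout = layout, scene = sc, manifests = manifests)
}
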