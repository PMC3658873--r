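## Genome browser map: chromosomes stacked vertically, per-gene expression
## glyphs at genomic coordinates, order-preserving glyph spreading with
## leader lines, and additive alpha highlight markers.

#' Read gene annotations from BED or GFF3
#'
#' Coordinates are converted to the 0-based half-open convention
#' internally (BED's native convention; GFF3's 1-based closed intervals
#' are shifted on ingest).
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @param format Override the extension-based format guess.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`.
#' @export
read_gene_annotations <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot guess annotation format from '.", ext,
                          "'; pass format="))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("the rtracklayer package is required to read ", format, " files")
  }
  gr <- rtracklayer::import(path, format = format)
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else if (!is.null(gr$ID)) as.character(gr$ID)
         else if (!is.null(gr$Name)) as.character(gr$Name)
         else paste0("feature_", seq_along(gr))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ids,
    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("zero-length annotation in ", path)
  out
}

#' Natural chromosome ordering
#'
#' Orders chromosome names numerically where numeric (1, 2, ..., 10, ...),
#' then X, Y, MT, then anything else alphabetically. `chr` prefixes are
#' ignored for ranking.
#'
#' @param chroms Character vector of chromosome names.
#' @return The unique names in natural order.
#' @export
natural_chrom_order <- function(chroms) {
  u <- unique(chroms)
  core <- sub("^chr", "", u, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(core))
  special <- match(toupper(core), c("X", "Y", "MT", "M"))
  key1 <- ifelse(!is.na(num), 0L, ifelse(!is.na(special), 1L, 2L))
  key2 <- ifelse(!is.na(num), num, ifelse(!is.na(special), special, 0))
  u[order(key1, key2, core)]
}

#' Linear genome track layout
#'
#' Chromosomes are arranged vertically in natural order, each extending
#' horizontally with a shared base-pair scale (the longest chromosome
#' spans the full world width); base pair to x is linear with no space
#' warping or distortion. Each gene's anchor x is the linear image of its
#' interval midpoint.
#'
#' @param ann Annotation data.frame (see [read_gene_annotations()]).
#' @param chrom_lengths Optional named vector of chromosome lengths in bp;
#'   defaults to the maximum annotated end per chromosome.
#' @return An object of class `gm_genome_layout`: `genes` data.frame
#'   (`gene_id`, `chrom`, `strand`, `anchor_x`, `x0`, `x1`, `y_axis`,
#'   `band_y0`, `band_y1`, `band_width`, `disp_x0`, `disp_x1`,
#'   `leader_from_x`, `leader_to_x`) and `chroms` data.frame.
#' @export
layout_genome <- function(ann, chrom_lengths = NULL) {
  if (nrow(ann) == 0) stop("no annotations supplied")
  chroms <- natural_chrom_order(ann$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc) {
      max(ann$end[ann$chrom == cc])
    }, numeric(1))
  }
  chrom_lengths <- chrom_lengths[chroms]
  l_max <- max(chrom_lengths)
  nc <- length(chroms)
  band_h <- 1 / nc
  chrom_df <- data.frame(
    chrom = chroms, length = as.numeric(chrom_lengths),
    band_y0 = (seq_len(nc) - 1) * band_h, band_y1 = seq_len(nc) * band_h,
    y_axis = ((seq_len(nc) - 1) + 0.5) * band_h,
    band_width = as.numeric(chrom_lengths) / l_max,
    stringsAsFactors = FALSE)
  ci <- match(ann$chrom, chroms)
  genes <- data.frame(
    gene_id = ann$gene_id, chrom = ann$chrom, strand = ann$strand,
    anchor_x = (ann$start + ann$end) / 2 / l_max,
    x0 = ann$start / l_max, x1 = ann$end / l_max,
    y_axis = chrom_df$y_axis[ci],
    band_y0 = chrom_df$band_y0[ci], band_y1 = chrom_df$band_y1[ci],
    band_width = chrom_df$band_width[ci],
    stringsAsFactors = FALSE)
  genes <- genes[order(ci, genes$anchor_x, genes$gene_id), ]
  rownames(genes) <- NULL
  genes$disp_x0 <- genes$x0
  genes$disp_x1 <- genes$x1
  genes$leader_from_x <- genes$anchor_x
  genes$leader_to_x <- genes$anchor_x
  structure(list(genes = genes, chroms = chrom_df, l_max = l_max),
            class = "gm_genome_layout")
}

## Exact order-preserving minimal-displacement 1D packing: minimize
## sum (x_i - a_i)^2 subject to x_{i+1} - x_i >= (w_i + w_{i+1})/2.
## Substituting t_i = a_i - c_i (c = cumulative required spacing) reduces
## the problem to unweighted isotonic regression, solved by the
## pool-adjacent-violators (cluster-and-average) sweep, which is exact.
pava_pack <- function(anchors, widths) {
  n <- length(anchors)
  if (n == 1) return(anchors)
  spacing <- (widths[-n] + widths[-1]) / 2
  cum <- c(0, cumsum(spacing))
  t <- anchors - cum
  # PAVA: maintain blocks of (sum, count); merge while means decrease
  bs <- numeric(n); bc <- integer(n); k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    bs[k] <- t[i]; bc[k] <- 1L
    while (k > 1L && bs[k] / bc[k] < bs[k - 1L] / bc[k - 1L]) {
      bs[k - 1L] <- bs[k - 1L] + bs[k]
      bc[k - 1L] <- bc[k - 1L] + bc[k]
      k <- k - 1L
    }
  }
  fit <- rep(bs[seq_len(k)] / bc[seq_len(k)], bc[seq_len(k)])
  fit + cum
}

#' Spread genome glyphs to resolve overlap
#'
#' In high-density regions the space available to render a gene at the
#' deepest zoom is insufficient; glyphs are therefore widened to a minimum
#' on-screen width and de-overlapped along each chromosome by an exact
#' order-preserving minimal-displacement pass (pool-adjacent-violators).
#' Displaced glyphs keep a leader line back to their true genomic anchor.
#'
#' @param layout A `gm_genome_layout`.
#' @param min_width Minimum glyph width in pixels at `z_max`.
#' @param pyramid The target [tile_pyramid()] (supplies `tile_size`,
#'   `z_max` hence the world size of `min_width`).
#' @return The layout with updated `disp_x0`, `disp_x1`, `leader_*`
#'   columns; genomic order along x is preserved and no two glyphs on a
#'   chromosome overlap at `z_max`.
#' @export
spread_glyphs <- function(layout, min_width = 8, pyramid = tile_pyramid(4)) {
  stopifnot(min_width > 0)
  g <- layout$genes
  w_min <- min_width / (pyramid$tile_size * 2^pyramid$z_max)
  for (cc in unique(g$chrom)) {
    idx <- which(g$chrom == cc)
    w <- pmax(g$x1[idx] - g$x0[idx], w_min)
    bw <- g$band_width[idx[1]]
    if (sum(w) > bw) {
      # smallest z_max at which the minimum width fits the band
      need <- function(z) sum(pmax(g$x1[idx] - g$x0[idx],
                                   min_width / (pyramid$tile_size * 2^z)))
      z_fit <- pyramid$z_max
      while (z_fit <= 16 && need(z_fit) > bw) z_fit <- z_fit + 1
      stop("chromosome ", cc, ": total glyph width ", signif(sum(w), 3),
           " exceeds its band width ", signif(bw, 3),
           "; the smallest z_max that fits is ", z_fit)
    }
    x <- pava_pack(g$anchor_x[idx], w)
    # clamp into the chromosome band (feasible since sum(w) <= bw);
    # both walls are monotone, so clamping preserves the spacing
    x <- pmax(x, cumsum(w) - w / 2)                  # left wall at 0
    x <- pmin(x, bw - rev(cumsum(rev(w))) + w / 2)   # right wall at bw
    g$disp_x0[idx] <- x - w / 2
    g$disp_x1[idx] <- x + w / 2
    g$leader_from_x[idx] <- x
    g$leader_to_x[idx] <- g$anchor_x[idx]
  }
  layout$genes <- g
  layout
}

#' Radial highlight marker icon
#'
#' An opacity raster with high alpha at the center fading linearly to zero
#' at the borders. Composited source-over, co-located markers amplify each
#' other, so regions dense in highlighted genes stand out at overview
#' zooms while central opacity saturates below 1.
#'
#' @param radius Icon radius in pixels (>= 1).
#' @param peak_opacity Center opacity in `[0, 1]`.
#' @return An object of class `gm_highlight_icon`: a
#'   `(2*radius+1)^2` opacity matrix with attributes `radius`,
#'   `peak_opacity`.
#' @export
make_highlight_icon <- function(radius, peak_opacity = 0.5) {
  if (radius < 1) stop("radius must be >= 1")
  if (peak_opacity < 0 || peak_opacity > 1) {
    stop("peak_opacity must lie in [0, 1]")
  }
  n <- 2 * radius + 1
  d <- sqrt(outer((seq_len(n) - radius - 1)^2,
                  (seq_len(n) - radius - 1)^2, "+"))
  a <- peak_opacity * pmax(1 - d / radius, 0)
  structure(a, class = "gm_highlight_icon", radius = radius,
            peak_opacity = peak_opacity)
}

#' Composite highlight icons source-over
#'
#' @param icons List of opacity matrices (all the same size) stacked at
#'   the same location.
#' @return The combined opacity matrix `1 - prod(1 - a_k)`.
#' @export
composite_icons <- function(icons) {
  out <- 1 - Reduce(function(acc, a) acc * (1 - unclass(a)), icons,
                    accumulate = FALSE, right = FALSE,
                    init = matrix(1, nrow(icons[[1]]), ncol(icons[[1]])))
  out
}

#' Genome browser scene
#'
#' Chromosome axis lines, per-gene expression glyphs (heatmap strips when
#' an expression matrix is joined, strand-colored boxes otherwise) at
#' their display positions, leader lines to true anchors, and optional
#' additive highlight markers for an externally supplied gene list.
#' Per-gene glyph identity is preserved at every zoom: glyphs are never
#' aggregated across zoom levels.
#'
#' @param layout A (typically spread) `gm_genome_layout`.
#' @param expr Optional expression matrix joined on `gene_id`.
#' @param highlight Optional character vector of gene ids to mark.
#' @param background Background color.
#' @return A [scene()].
#' @export
genome_scene <- function(layout, expr = NULL, highlight = NULL,
                         background = "white") {
  g <- layout$genes
  chroms <- layout$chroms
  glyph_h <- min(0.25 / nrow(chroms), 0.04)
  prims <- list()
  for (i in seq_len(nrow(chroms))) {
    prims[[length(prims) + 1L]] <-
      prim_segment(0, chroms$y_axis[i], chroms$band_width[i],
                   chroms$y_axis[i], lwd = 0.0015, col = "grey40")
  }
  for (i in seq_len(nrow(g))) {
    y0 <- g$y_axis[i] - glyph_h - 0.002
    # leader line: from the displayed glyph position down to the true anchor
    prims[[length(prims) + 1L]] <-
      prim_segment(g$leader_from_x[i], g$y_axis[i] - 0.002,
                   g$leader_to_x[i], g$y_axis[i], lwd = 0.001,
                   col = "grey55")
    if (!is.null(expr) && g$gene_id[i] %in% rownames(expr)) {
      gl <- expression_colormap(expr[g$gene_id[i], , drop = FALSE],
                                range_from = expr)
      prims[[length(prims) + 1L]] <-
        prim_cellgrid(g$disp_x0[i], y0, g$disp_x1[i],
                      g$y_axis[i] - 0.002, gl, border_min_px = 4)
    } else {
      col <- switch(g$strand[i], `+` = "#1B7837", `-` = "#762A83", "grey35")
      prims[[length(prims) + 1L]] <-
        prim_rect(g$disp_x0[i], y0, g$disp_x1[i], g$y_axis[i] - 0.002, col)
    }
  }
  if (!is.null(highlight)) {
    hi <- g[g$gene_id %in% highlight, , drop = FALSE]
    for (i in seq_len(nrow(hi))) {
      prims[[length(prims) + 1L]] <-
        prim_glow(hi$anchor_x[i], hi$y_axis[i], r = 0.03, peak = 0.5,
                  col = "#FFD700")
    }
  }
  scene(prims, background = background)
}

#' Build all genome browser artifacts
#'
#' @param ann Annotation data.frame.
#' @param expr Optional expression matrix joined on gene id.
#' @param pyramid Target pyramid (drives the glyph spreading scale).
#' @param min_width Minimum glyph width in pixels at the deepest zoom.
#' @param highlight Optional gene-id list to mark.
#' @return List with `layout`, `scene`, `manifests` (gene anchors
#'   `{gene_id: [nx, ny]}` plus per-zoom label visibility).
#' @export
build_genome <- function(ann, expr = NULL, pyramid = tile_pyramid(4),
                         min_width = 8, highlight = NULL) {
  layout <- spread_glyphs(layout_genome(ann), min_width = min_width,
                          pyramid = pyramid)
  sc <- genome_scene(layout, expr = expr, highlight = highlight)
  g <- layout$genes
  anchors <- stats::setNames(
    lapply(seq_len(nrow(g)), function(i) c(g$anchor_x[i], g$y_axis[i])),
    g$gene_id)
  # gene-name labels are client-drawn; visible once glyphs are >= 30 px wide
  label_zoom <- vapply(seq_len(nrow(g)), function(i) {
    w <- g$disp_x1[i] - g$disp_x0[i]
    z <- 0
    while (w * pyramid$tile_size * 2^z < 30 && z <= pyramid$z_max) z <- z + 1
    z
  }, numeric(1))
  manifests <- list(anchors = anchors,
                    label_min_zoom = stats::setNames(label_zoom, g$gene_id),
                    chromosomes = layout$chroms)
  list(layout = layout, scene = sc, manifests = manifests)
}
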