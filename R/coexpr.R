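## Gene co-expression map: genes placed in the plane by expression
## similarity, with a superimposed hierarchical clustering whose cut level
## is linked to zoom (groups become smaller and tighter when zooming in).

#' Hierarchical clustering of expression profiles
#'
#' Average-linkage agglomerative clustering on the co-expression distance
#' ([expression_dist]). Deterministic given input order.
#'
#' @param m Expression matrix (genes in rows).
#' @inheritParams expression_distance
#' @return An [stats::hclust] tree over the genes.
#' @export
build_dendrogram <- function(m, method = c("pearson", "euclidean")) {
  if (nrow(m) < 2) stop("need at least 2 genes to cluster")
  stats::hclust(expression_dist(m, method = method), method = "average")
}

#' Zoom-linked dendrogram cuts
#'
#' Assigns one dendrogram cut per zoom level so that cluster granularity
#' increases with zoom. The cut at `z_min` sits at the root height (one
#' all-encompassing cluster); subsequent cut heights decrease
#' geometrically down to just below a low quantile of the merge heights,
#' so partitions are nested and cluster counts never decrease with zoom.
#'
#' @param tree An [stats::hclust] tree (or `NULL` for a degenerate
#'   single-gene input, handled via `labels`).
#' @param z_min,z_max Zoom range (inclusive, `z_min <= z_max`).
#' @param floor_quantile Merge-height quantile used as the finest cut
#'   height (default 0.05).
#' @param labels Leaf labels, needed only for the degenerate 1-leaf case.
#' @return List of cuts; each cut is a list with `zoom`, `height` and
#'   `partition` (named integer vector gene -> cluster id).
#' @export
cuts_for_zoom <- function(tree, z_min, z_max, floor_quantile = 0.05,
                          labels = NULL) {
  if (z_min > z_max) stop("z_min must be <= z_max")
  zooms <- z_min:z_max
  if (is.null(tree)) {
    # degenerate single-leaf tree: one singleton cluster at every zoom
    part <- stats::setNames(1L, labels %||% "gene")
    return(lapply(zooms, function(z) list(zoom = z, height = 0,
                                          partition = part)))
  }
  h_root <- max(tree$height)
  h_floor <- max(stats::quantile(tree$height, floor_quantile, names = FALSE),
                 .Machine$double.eps)
  nz <- length(zooms)
  heights <- if (nz == 1) h_root else {
    h_root * (h_floor / h_root)^((zooms - z_min) / (nz - 1))
  }
  lapply(seq_along(zooms), function(i) {
    h <- heights[i]
    part <- if (i == 1) {
      stats::setNames(rep(1L, length(tree$labels)), tree$labels)
    } else {
      stats::cutree(tree, h = h)
    }
    list(zoom = zooms[i], height = h, partition = part)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Planar embedding of genes by expression similarity
#'
#' Places genes so that planar proximity reflects expression similarity,
#' with discrete cluster structure: cluster centers are positioned by
#' classical multidimensional scaling of the inter-centroid co-expression
#' distances, each cluster occupies a disc whose radius grows with
#' membership, genes are arranged deterministically on a sunflower spiral
#' inside their cluster's disc, and an iterative (seedless) repulsion pass
#' makes discs of distinct clusters disjoint.
#'
#' @param m Expression matrix (genes in rows).
#' @param partition Named integer vector gene -> cluster id (typically the
#'   finest cut from [cuts_for_zoom()]).
#' @param margin Empty world margin kept around the layout.
#' @return An object of class `gm_embedding`: list with `positions`
#'   (n x 2 matrix of world coordinates, rownames = gene ids),
#'   `cluster_of` (the partition), `centers` (k x 2) and `radii` (k).
#' @export
embed_genes <- function(m, partition, margin = 0.08) {
  stopifnot(nrow(m) >= 1, all(rownames(m) %in% names(partition)))
  partition <- partition[rownames(m)]
  ids <- sort(unique(partition))
  k <- length(ids)
  n <- nrow(m)

  # cluster centroid profiles and their MDS placement
  centroids <- t(vapply(ids, function(cl) {
    aggregate_profile(m[partition == cl, , drop = FALSE])
  }, numeric(ncol(m))))
  sizes <- as.integer(table(factor(partition, levels = ids)))

  centers <- if (k == 1) {
    matrix(0.5, 1, 2)
  } else {
    d <- tryCatch(expression_dist(centroids),
                  error = function(e) stats::dist(centroids))
    if (max(d) < 1e-12) {
      warning("all cluster centroids identical; falling back to uniform ",
              "angular placement")
      ang <- 2 * pi * (seq_len(k) - 1) / k
      cbind(cos(ang), sin(ang))
    } else {
      # rank-deficient configurations (fewer positive eigenvalues than
      # requested axes) are handled below by zero-padding
      xy <- suppressWarnings(stats::cmdscale(d, k = min(2, k - 1)))
      if (ncol(xy) == 1) xy <- cbind(xy, 0)
      if (max(stats::dist(xy)) < 1e-12) {
        warning("degenerate MDS configuration; falling back to uniform ",
                "angular placement")
        ang <- 2 * pi * (seq_len(k) - 1) / k
        xy <- cbind(cos(ang), sin(ang))
      }
      # fix the reflection ambiguity: largest cluster left of second largest
      o <- order(-sizes)
      if (k >= 2 && xy[o[1], 1] > xy[o[2], 1]) xy[, 1] <- -xy[, 1]
      xy
    }
  }

  # disc radii: area proportional to membership, total area ~ 30% of world
  radii <- sqrt(sizes / n) * 0.3
  centers <- normalize_box(centers, margin + max(radii))
  centers <- separate_discs(centers, radii, gap = 0.01)

  positions <- matrix(NA_real_, n, 2,
                      dimnames = list(rownames(m), c("x", "y")))
  golden <- pi * (3 - sqrt(5))
  for (ci in seq_along(ids)) {
    members <- which(partition == ids[ci])
    nm <- length(members)
    # deterministic sunflower placement, inner-first by centroid similarity
    dc <- vapply(members, function(g) {
      sqrt(sum((m[g, ] - centroids[ci, ])^2))
    }, numeric(1))
    ord <- members[order(dc, rownames(m)[members])]
    j <- seq_len(nm)
    rad <- radii[ci] * 0.9 * sqrt((j - 0.5) / nm)
    ang <- j * golden
    positions[ord, 1] <- centers[ci, 1] + rad * cos(ang)
    positions[ord, 2] <- centers[ci, 2] + rad * sin(ang)
  }
  positions[] <- pmin(1 - 1e-9, pmax(0, positions))
  structure(list(positions = positions, cluster_of = partition,
                 centers = centers, radii = radii, cluster_ids = ids),
            class = "gm_embedding")
}

## Affinely map points into [margin, 1 - margin]^2 preserving aspect.
normalize_box <- function(xy, margin) {
  margin <- min(margin, 0.45)
  rng <- apply(xy, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-12)
  ctr <- colMeans(rng)
  sweep(sweep(xy, 2, ctr), 2, rep(span, 2), "/") * (1 - 2 * margin) + 0.5
}

## Deterministic pairwise repulsion until discs are disjoint (or the
## iteration cap is hit); pairs processed in cluster-id order, seedless.
separate_discs <- function(centers, radii, gap = 0.01, max_iter = 200) {
  k <- nrow(centers)
  if (k < 2) return(centers)
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- centers[j, ] - centers[i, ]
        d <- sqrt(sum(v^2))
        need <- radii[i] + radii[j] + gap
        if (d < need) {
          dir <- if (d < 1e-12) c(1, 0) else v / d
          push <- (need - d) / 2
          centers[i, ] <- centers[i, ] - dir * push
          centers[j, ] <- centers[j, ] + dir * push
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  # keep everything inside the world
  lo <- pmax(radii, 0)
  for (ax in 1:2) {
    centers[, ax] <- pmin(1 - lo - 1e-3, pmax(lo + 1e-3, centers[, ax]))
  }
  centers
}

#' Cluster boundary polygon
#'
#' Convex hull of the member positions, padded outward from the hull
#' centroid by a fixed world margin.
#'
#' @param pts n x 2 matrix of member positions.
#' @param pad Outward padding in world units.
#' @return Matrix of hull vertices (closed implicitly).
#' @export
cluster_boundary <- function(pts, pad = 0.01) {
  if (nrow(pts) == 1) {
    a <- seq(0, 2 * pi, length.out = 9)[-9]
    return(cbind(pts[1, 1] + pad * cos(a), pts[1, 2] + pad * sin(a)))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  ctr <- colMeans(hull)
  out <- t(apply(hull, 1, function(p) {
    v <- p - ctr
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) p else p + v / nv * pad
  }))
  out
}

#' Scene for the co-expression map
#'
#' Semantic-zoom scene: every gene is always drawn (as a dot below the
#' glyph-zoom threshold, as a per-gene heatmap strip at or above it); the
#' zoom level's cluster cut contributes one boundary polygon and one
#' aggregated-profile glyph per cluster.
#'
#' @param m Expression matrix.
#' @param embedding A `gm_embedding` from [embed_genes()].
#' @param cuts Cuts from [cuts_for_zoom()].
#' @param glyph_zoom Zoom level at/above which per-gene glyphs replace dots.
#' @param colormap Function mapping a numeric matrix to an
#'   `nr x nc x 3` color array (default [expression_colormap()]).
#' @param background Scene background color.
#' @return A [scene()].
#' @export
coexpr_scene <- function(m, embedding, cuts, glyph_zoom = 3,
                         colormap = expression_colormap, background = "white") {
  cut_by_zoom <- stats::setNames(cuts, vapply(cuts, function(cc) {
    as.character(cc$zoom)
  }, character(1)))
  pos <- embedding$positions
  cols_m <- colormap(m)
  scene(function(z) {
    prims <- list()
    cc <- cut_by_zoom[[as.character(z)]]
    if (!is.null(cc)) {
      part <- cc$partition[rownames(pos)]
      for (cl in sort(unique(part))) {
        mem <- which(part == cl)
        hull <- cluster_boundary(pos[mem, , drop = FALSE])
        prims[[length(prims) + 1L]] <-
          prim_polyline(hull[, 1], hull[, 2], lwd = 0.003,
                        col = "grey60", closed = TRUE)
        ctr <- colMeans(pos[mem, , drop = FALSE])
        prof <- aggregate_profile(m[mem, , drop = FALSE])
        gl <- colormap(matrix(prof, nrow = 1,
                              dimnames = list(NULL, colnames(m))),
                       range_from = m)
        gw <- 0.04
        prims[[length(prims) + 1L]] <-
          prim_cellgrid(ctr[1] - gw / 2, ctr[2] - gw / 8,
                        ctr[1] + gw / 2, ctr[2] + gw / 8, gl,
                        border_min_px = 4)
      }
    }
    if (z < glyph_zoom) {
      for (g in seq_len(nrow(pos))) {
        prims[[length(prims) + 1L]] <-
          prim_disc(pos[g, 1], pos[g, 2], r = 0.004, col = "grey20")
      }
    } else {
      gw <- 0.02
      for (g in seq_len(nrow(pos))) {
        gl <- array(cols_m[g, , , drop = FALSE], dim = c(1, ncol(m), 3))
        prims[[length(prims) + 1L]] <-
          prim_cellgrid(pos[g, 1] - gw / 2, pos[g, 2] - gw / 6,
                        pos[g, 1] + gw / 2, pos[g, 2] + gw / 6, gl,
                        border_min_px = 4)
      }
    }
    prims
  }, background = background)
}

#' Build all co-expression map artifacts
#'
#' Convenience pipeline: dendrogram, zoom cuts, embedding, scene and the
#' JSON-ready manifests (gene positions, per-zoom memberships, per-cluster
#' aggregated profiles, searchable gene index).
#'
#' @param m Expression matrix.
#' @param z_min,z_max Zoom range.
#' @param glyph_zoom See [coexpr_scene()].
#' @return List with `tree`, `cuts`, `embedding`, `scene`, `manifests`.
#' @export
build_coexpr <- function(m, z_min = 0, z_max = 4, glyph_zoom = 3) {
  tree <- build_dendrogram(m)
  cuts <- cuts_for_zoom(tree, z_min, z_max)
  emb <- embed_genes(m, cuts[[length(cuts)]]$partition)
  sc <- coexpr_scene(m, emb, cuts, glyph_zoom = glyph_zoom)
  membership <- lapply(cuts, function(cc) {
    list(zoom = cc$zoom, clusters = split(names(cc$partition), cc$partition))
  })
  profiles <- lapply(cuts, function(cc) {
    lapply(split(names(cc$partition), cc$partition), function(g) {
      as.numeric(aggregate_profile(m[g, , drop = FALSE]))
    })
  })
  manifests <- list(
    positions = stats::setNames(
      lapply(seq_len(nrow(emb$positions)), function(i) {
        as.numeric(emb$positions[i, ])
      }), rownames(emb$positions)),
    membership = membership,
    cluster_profiles = profiles,
    conditions = colnames(m),
    gene_index = sort(rownames(m)))
  list(tree = tree, cuts = cuts, embedding = emb, scene = sc,
       manifests = manifests)
}
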