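## White-matter tract map: cluster 3D curves by a curve-similarity
## measure, pick centroid tracts, and project onto the three anatomical
## planes for tiling. Axis convention: x = left-right, y =
## posterior-anterior, z = inferior-superior; sagittal drops x, coronal
## drops y, transverse drops z.

#' Read tracts from JSON
#'
#' Expects `[{"id": str, "points": [[x, y, z], ...]}, ...]`.
#'
#' @param path JSON tract file.
#' @return List of tracts; each a list with `id` and `points`
#'   (`n x 3` matrix).
#' @export
read_tracts <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(t) {
    pts <- do.call(rbind, lapply(t$points, unlist))
    if (nrow(pts) < 2 || !all(is.finite(pts))) {
      stop("tract ", t$id, " needs >= 2 finite 3D points")
    }
    list(id = t$id, points = pts)
  })
}

#' Curve distance between two tracts
#'
#' Symmetrized mean closest-point distance: the mean over points of `a` of
#' the distance to the nearest point of `b`, averaged with the converse.
#' Symmetric, and zero exactly when the two point sets coincide as sets.
#' This is the standard inter-streamline measure in tractography
#' clustering.
#'
#' @param a,b Tracts (lists with a `points` matrix) or bare `n x 3`
#'   matrices.
#' @return Non-negative distance in the tracts' spatial units.
#' @export
curve_distance <- function(a, b) {
  pa <- if (is.list(a)) a$points else a
  pb <- if (is.list(b)) b$points else b
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Pairwise curve-distance matrix
#'
#' @param tracts List of tracts.
#' @return Symmetric matrix of [curve_distance()] values.
#' @export
curve_distance_matrix <- function(tracts) {
  n <- length(tracts)
  m <- matrix(0, n, n)
  ids <- vapply(tracts, `[[`, character(1), "id")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- curve_distance(tracts[[i]], tracts[[j]])
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Cluster tracts and select centroid tracts
#'
#' Average-linkage agglomerative clustering on the curve-distance matrix,
#' cut into `k` clusters. Each cluster's centroid tract is the member
#' minimizing the summed curve distance to its co-members; per-cluster
#' statistics (member count, mean curve length, mean distance to the
#' centroid) are precomputed for the detail records.
#'
#' @param tracts List of tracts.
#' @param k Number of clusters (`1 <= k <= length(tracts)`).
#' @param dmat Optional precomputed [curve_distance_matrix()].
#' @return List of clusters; each a list with `members` (ids),
#'   `centroid_id`, and `stats` (`n`, `mean_length`,
#'   `mean_centroid_distance`).
#' @export
cluster_tracts <- function(tracts, k, dmat = NULL) {
  n <- length(tracts)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k must be <= number of tracts")
  ids <- vapply(tracts, `[[`, character(1), "id")
  if (is.null(dmat)) dmat <- curve_distance_matrix(tracts)
  labels <- if (n == 1) 1L else {
    stats::cutree(stats::hclust(stats::as.dist(dmat), method = "average"),
                  k = k)
  }
  lens <- vapply(tracts, function(t) {
    p <- t$points
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                      p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  lapply(sort(unique(labels)), function(cl) {
    mem <- which(labels == cl)
    sums <- rowSums(dmat[mem, mem, drop = FALSE])
    cen <- mem[order(sums, ids[mem])[1]]
    list(members = ids[mem], centroid_id = ids[cen],
         stats = list(n = length(mem),
                      mean_length = mean(lens[mem]),
                      mean_centroid_distance =
                        mean(dmat[cen, mem])))
  })
}

plane_axis <- function(plane) {
  switch(plane, sagittal = 1L, coronal = 2L, transverse = 3L,
         stop("plane must be one of sagittal, coronal, transverse"))
}

#' Drop a plane's axis from 3D points
#'
#' Orthogonal projection onto an anatomical plane: the dropped coordinate
#' is zeroed, so applying the same projection twice is idempotent.
#'
#' @param points `n x 3` matrix.
#' @param plane `"sagittal"`, `"coronal"` or `"transverse"`.
#' @return `n x 3` matrix with the plane's axis zeroed.
#' @export
drop_axis <- function(points, plane) {
  points[, plane_axis(plane)] <- 0
  points
}

#' Project tract clusters onto an anatomical plane
#'
#' Centroid tracts become 2D polylines; each member contributes two thin
#' endpoint links from the centroid's endpoints to the member's projected
#' endpoints. Coordinates are normalized into the world square using a
#' bounding box shared by all tracts (with an epsilon guard for
#' degenerate, zero-range axes).
#'
#' @param clusters From [cluster_tracts()].
#' @param tracts The tract list the clusters refer to.
#' @param plane `"sagittal"`, `"coronal"` or `"transverse"`.
#' @param margin World margin around the drawing.
#' @return An object of class `gm_projection`: list with `plane`,
#'   `centroids` (per cluster, `n x 2` world polyline), `links` (per
#'   cluster, list of 2-point segments), `to_world` (the mapping function
#'   used).
#' @export
project_tracts <- function(clusters, tracts, plane, margin = 0.05) {
  if (length(clusters) == 0) stop("no clusters to project")
  ax <- plane_axis(plane)
  keep <- setdiff(1:3, ax)
  ids <- vapply(tracts, `[[`, character(1), "id")
  all_pts <- do.call(rbind, lapply(tracts, `[[`, "points"))[, keep,
                                                            drop = FALSE]
  lo <- apply(all_pts, 2, min)
  hi <- apply(all_pts, 2, max)
  span <- max(hi - lo, 1e-9)
  if (any(hi - lo <= 1e-12)) {
    warning("degenerate extent on a kept axis of the ", plane,
            " plane; epsilon-guarded scaling used")
  }
  to_world <- function(p3) {
    p <- p3[, keep, drop = FALSE]
    # horizontal = first kept axis; vertical flipped so "up" is up
    u <- (p[, 1] - lo[1]) / span
    v <- (hi[2] - p[, 2]) / span
    cbind(u * (1 - 2 * margin) + margin, v * (1 - 2 * margin) + margin)
  }
  proj <- lapply(clusters, function(cl) {
    cen <- tracts[[match(cl$centroid_id, ids)]]$points
    cen2 <- to_world(cen)
    links <- list()
    for (mid in cl$members) {
      mp <- tracts[[match(mid, ids)]]$points
      mp2 <- to_world(mp)
      links[[length(links) + 1L]] <- rbind(cen2[1, ], mp2[1, ])
      links[[length(links) + 1L]] <- rbind(cen2[nrow(cen2), ],
                                           mp2[nrow(mp2), ])
    }
    list(centroid = cen2, links = links, centroid_id = cl$centroid_id)
  })
  structure(list(plane = plane,
                 centroids = lapply(proj, `[[`, "centroid"),
                 links = lapply(proj, `[[`, "links"),
                 centroid_ids = vapply(proj, `[[`, character(1),
                                       "centroid_id"),
                 to_world = to_world),
            class = "gm_projection")
}

#' Scene for one anatomical plane
#'
#' @param projection A `gm_projection`.
#' @param background Background color.
#' @return A [scene()].
#' @export
tract_scene <- function(projection, background = "white") {
  palette <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
               "#A65628", "#F781BF", "#666666")
  prims <- list()
  for (i in seq_along(projection$centroids)) {
    col <- palette[(i - 1) %% length(palette) + 1]
    for (lk in projection$links[[i]]) {
      prims[[length(prims) + 1L]] <-
        prim_segment(lk[1, 1], lk[1, 2], lk[2, 1], lk[2, 2],
                     lwd = 0.0008, col = col, alpha = 0.5)
    }
    cen <- projection$centroids[[i]]
    prims[[length(prims) + 1L]] <-
      prim_polyline(cen[, 1], cen[, 2], lwd = 0.004, col = col)
  }
  scene(prims, background = background)
}

#' Build all tract map artifacts (three planes)
#'
#' @param tracts List of tracts.
#' @param k Cluster count.
#' @return List with `clusters`, per-plane `projections` and `scenes`,
#'   and `manifests` (per-cluster details: stats, member list, world
#'   centroid trajectory per plane).
#' @export
build_tracts <- function(tracts, k) {
  dmat <- curve_distance_matrix(tracts)
  clusters <- cluster_tracts(tracts, k, dmat = dmat)
  planes <- c("sagittal", "coronal", "transverse")
  projections <- stats::setNames(lapply(planes, function(pl) {
    project_tracts(clusters, tracts, pl)
  }), planes)
  scenes <- lapply(projections, tract_scene)
  details <- lapply(seq_along(clusters), function(i) {
    list(cluster = i, stats = clusters[[i]]$stats,
         members = clusters[[i]]$members,
         centroid_id = clusters[[i]]$centroid_id,
         centroid_trajectory = lapply(projections, function(pr) {
           unname(apply(pr$centroids[[i]], 1, as.numeric, simplify = FALSE))
         }))
  })
  list(clusters = clusters, projections = projections, scenes = scenes,
       manifests = list(details = details))
}
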