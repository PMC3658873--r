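## Protein interaction network map: relevance scoring (intrinsic +
## diffused), zoom stratification (the city-versus-town map analogy),
## force-directed base layout, and vertex splitting so that every
## interaction is locally visible at high zoom.

#' Read an interaction graph
#'
#' Accepts a two-column delimited edge list (tab or comma, optional
#' header) or a GraphML file. The graph is simplified on load: self-loops
#' and duplicate edges are dropped.
#'
#' @param path Edge list or `.graphml` file.
#' @param node_weights Optional named numeric vector (or two-column
#'   data.frame) of intrinsic node relevance weights.
#' @return An [igraph::igraph] object with a `weight` vertex attribute
#'   when weights were supplied.
#' @export
read_interaction_graph <- function(path, node_weights = NULL) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  if (tolower(tools::file_ext(path)) == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = FALSE, sep = sep,
                            stringsAsFactors = FALSE,
                            col.names = c("from", "to"))
    if (identical(tolower(df$from[1]), "from")) df <- df[-1, ]
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(node_weights)) {
    if (is.data.frame(node_weights)) {
      node_weights <- stats::setNames(node_weights[[2]], node_weights[[1]])
    }
    w <- node_weights[igraph::V(g)$name]
    if (anyNA(w)) stop("missing weights for some nodes")
    igraph::V(g)$weight <- as.numeric(w)
  }
  g
}

#' Node relevance: intrinsic plus diffused
#'
#' A node's relevance combines its intrinsic importance (a supplied weight
#' or, failing that, its degree) with importance diffused from its
#' neighborhood: one diffusion round
#' `r_i = (1 - alpha) * b_i + alpha * mean(b_j, j ~ i)` (isolated nodes
#' keep `r_i = b_i`), then min-max normalization to `[0, 1]`. At
#' `alpha = 0` this is pure intrinsic weight, at `alpha = 1` the
#' neighborhood mean.
#'
#' @param g An [igraph::igraph] graph.
#' @param alpha Diffusion mixing coefficient in `[0, 1]` (default 0.3).
#' @param weights Optional named intrinsic weights; defaults to the
#'   `weight` vertex attribute if present, else node degree.
#' @return An object of class `gm_relevance`: list with `score` (named,
#'   in `[0, 1]`, at least one node at 1), `raw` (pre-normalization),
#'   `alpha`.
#' @export
compute_relevance <- function(g, alpha = 0.3, weights = NULL) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  b <- if (!is.null(weights)) as.numeric(weights[nm])
       else if (!is.null(igraph::V(g)$weight)) igraph::V(g)$weight
       else as.numeric(igraph::degree(g))
  if (anyNA(b)) stop("missing intrinsic weights")
  adj <- igraph::as_adj_list(g, mode = "all")
  nbr_mean <- vapply(seq_along(adj), function(i) {
    ni <- as.integer(adj[[i]])
    if (length(ni) == 0) b[i] else mean(b[ni])
  }, numeric(1))
  raw <- (1 - alpha) * b + alpha * nbr_mean
  rng <- range(raw)
  score <- if (rng[1] == rng[2]) rep(1, length(raw)) else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(score = stats::setNames(score, nm),
                 raw = stats::setNames(raw, nm), alpha = alpha),
            class = "gm_relevance")
}

#' Stratify nodes over zoom levels by relevance
#'
#' Overview zooms show only the most relevant nodes (cities); each deeper
#' zoom adds less relevant ones (towns) until everything is visible at
#' `z_max`. The visible fraction doubles per zoom level (geometric
#' schedule); thresholds are score quantiles with ties kept, so strata are
#' nested and `z_max` is complete.
#'
#' @param relevance A `gm_relevance` from [compute_relevance()].
#' @param z_min,z_max Zoom range.
#' @return Named list (by zoom) of character vectors of visible node ids.
#' @export
stratify_by_zoom <- function(relevance, z_min, z_max) {
  if (z_min > z_max) stop("z_min must be <= z_max")
  s <- relevance$score
  out <- list()
  for (z in z_min:z_max) {
    frac <- 2^-(z_max - z)              # fraction of nodes visible
    thr <- stats::quantile(s, 1 - frac, names = FALSE, type = 1)
    if (z == z_max) thr <- min(s)
    out[[as.character(z)]] <- names(s)[s >= thr]
  }
  out
}

#' Deterministic force-directed base layout
#'
#' Fruchterman-Reingold layout under a fixed seed, rescaled into the unit
#' world with a margin.
#'
#' @param g An [igraph::igraph] graph.
#' @param seed Integer RNG seed.
#' @param margin World margin kept free around the layout.
#' @return `n x 2` matrix of world positions, rownames = node ids.
#' @export
layout_base <- function(g, seed = 1, margin = 0.08) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  if (igraph::vcount(g) == 1) {
    return(matrix(0.5, 1, 2, dimnames = list(nm, c("x", "y"))))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = 500)
  xy <- normalize_box(xy, margin)
  dimnames(xy) <- list(nm, c("x", "y"))
  xy
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Split vertices so every interaction is locally visible
#'
#' Force layouts may place connected proteins far apart, and zooming then
#' splits the interaction across views. For every edge whose endpoints lie
#' farther than `d_max` apart, a copy of the lower-relevance endpoint
#' (ties broken by id order; hubs stay put, per the cities-stay-put
#' analogy) is created near the higher-relevance endpoint, on a
#' collision-avoiding ring at distance `<= d_max / 2`. Every original edge
#' ends up with exactly one realization whose endpoint copies are within
#' `d_max` of each other.
#'
#' @param g An [igraph::igraph] graph.
#' @param positions Base layout (`n x 2`, rownames = node ids).
#' @param d_max Maximum realized edge length in world units (default 0.15).
#' @param relevance Optional `gm_relevance`; computed with defaults if
#'   missing.
#' @return An object of class `gm_split_layout`: `copies` data.frame
#'   (`copy_id`, `canonical`, `x`, `y`, `primary`), `realizations`
#'   data.frame (`from`, `to`, `from_copy`, `to_copy`, `dist`), and
#'   `registry` (canonical id -> copy ids).
#' @export
split_vertices <- function(g, positions, d_max = 0.15, relevance = NULL) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (is.null(relevance)) relevance <- compute_relevance(g)
  nm <- rownames(positions)
  stopifnot(!is.null(nm))
  copies <- data.frame(copy_id = paste0(nm, "/1"), canonical = nm,
                       x = positions[, 1], y = positions[, 2],
                       primary = TRUE, stringsAsFactors = FALSE,
                       row.names = NULL)
  n_copy <- stats::setNames(rep(1L, length(nm)), nm)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    # deterministic edge order
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1)]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  realizations <- data.frame(from = character(0), to = character(0),
                             from_copy = character(0),
                             to_copy = character(0), dist = numeric(0),
                             stringsAsFactors = FALSE)
  ring_angles <- 2 * pi * (0:15) / 16
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    pa <- positions[a, ]; pb <- positions[b, ]
    d <- sqrt(sum((pa - pb)^2))
    if (d <= d_max) {
      realizations[nrow(realizations) + 1L, ] <-
        list(a, b, paste0(a, "/1"), paste0(b, "/1"), d)
      next
    }
    # keep the higher-relevance endpoint, duplicate the other
    sa <- relevance$score[a]; sb <- relevance$score[b]
    keep <- if (sa > sb) a else if (sb > sa) b else min(a, b)
    dup <- if (keep == a) b else a
    pk <- positions[keep, ]
    placed <- FALSE
    for (rad in c(d_max / 4, d_max / 2 * 0.95)) {
      for (ang in ring_angles) {
        cand <- pk + rad * c(cos(ang), sin(ang))
        if (any(cand < 0) || any(cand >= 1)) next
        clash <- sqrt((copies$x - cand[1])^2 + (copies$y - cand[2])^2)
        if (min(clash) > d_max / 8) {
          n_copy[dup] <- n_copy[dup] + 1L
          cid <- paste0(dup, "/", n_copy[dup])
          copies[nrow(copies) + 1L, ] <-
            list(cid, dup, cand[1], cand[2], FALSE)
          rd <- sqrt(sum((pk - cand)^2))
          fc <- if (keep == a) paste0(a, "/1") else cid
          tc <- if (keep == a) cid else paste0(b, "/1")
          realizations[nrow(realizations) + 1L, ] <- list(a, b, fc, tc, rd)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      stop("could not place a copy of ", dup, " near ", keep,
           " without collisions; increase d_max (currently ", d_max, ")")
    }
  }
  registry <- split(copies$copy_id, copies$canonical)
  structure(list(copies = copies, realizations = realizations,
                 registry = registry, d_max = d_max),
            class = "gm_split_layout")
}

#' Export the copy-registry manifest
#'
#' The copies-list side panel needs, for every canonical protein, the
#' positions of all its copies and each copy's interactors, so clicking a
#' list item can jump to that copy.
#'
#' @param split A `gm_split_layout`.
#' @return List (JSON-ready) mapping canonical id to a list of
#'   `{copy, position, interactors}` records.
#' @export
export_copy_manifest <- function(split) {
  cp <- split$copies
  re <- split$realizations
  lapply(split$registry, function(cids) {
    lapply(cids, function(cid) {
      row <- cp[cp$copy_id == cid, ]
      inter <- unique(c(re$to[re$from_copy == cid],
                        re$from[re$to_copy == cid]))
      list(copy = cid, position = c(row$x, row$y),
           interactors = sort(inter))
    })
  })
}

#' Network map scene
#'
#' Per zoom level, draws the copies of visible-stratum nodes as discs
#' (radius grows with the square root of degree, capped) and the edges
#' both of whose realized endpoints belong to visible canonical nodes. An
#' edge appears at the first zoom where both its canonical endpoints are
#' visible.
#'
#' @param g The graph (for degrees).
#' @param split A `gm_split_layout`.
#' @param strata From [stratify_by_zoom()].
#' @param relevance A `gm_relevance` (colors nodes).
#' @param background Background color.
#' @return A [scene()].
#' @export
network_scene <- function(g, split, strata, relevance,
                          background = "white") {
  deg <- igraph::degree(g)
  nm <- igraph::V(g)$name
  names(deg) <- nm
  cp <- split$copies
  re <- split$realizations
  scene(function(z) {
    vis <- strata[[as.character(z)]]
    if (is.null(vis)) {
      vis <- if (z >= max(as.integer(names(strata)))) {
        strata[[length(strata)]]
      } else strata[[1]]
    }
    prims <- list()
    evis <- re$from %in% vis & re$to %in% vis
    for (i in which(evis)) {
      p1 <- cp[cp$copy_id == re$from_copy[i], ]
      p2 <- cp[cp$copy_id == re$to_copy[i], ]
      prims[[length(prims) + 1L]] <-
        prim_segment(p1$x, p1$y, p2$x, p2$y, lwd = 0.0015, col = "grey55")
    }
    cvis <- cp[cp$canonical %in% vis, , drop = FALSE]
    for (i in seq_len(nrow(cvis))) {
      r <- min(0.004 + 0.004 * sqrt(deg[cvis$canonical[i]]), 0.02)
      s <- relevance$score[cvis$canonical[i]]
      col <- grDevices::rgb(0.85 * s + 0.1, 0.25, 0.9 - 0.7 * s)
      prims[[length(prims) + 1L]] <-
        prim_disc(cvis$x[i], cvis$y[i], r, col)
    }
    prims
  }, background = background)
}

#' Build all network map artifacts
#'
#' @param g An [igraph::igraph] graph.
#' @param z_min,z_max Zoom range (default 0..4, five levels).
#' @param alpha Relevance diffusion mix.
#' @param d_max Vertex-splitting distance tolerance.
#' @param seed Layout seed.
#' @return List with `relevance`, `strata`, `positions`, `split`, `scene`,
#'   `manifests` (copy manifest plus per-node detail records).
#' @export
build_network <- function(g, z_min = 0, z_max = 4, alpha = 0.3,
                          d_max = 0.15, seed = 1) {
  rel <- compute_relevance(g, alpha = alpha)
  strata <- stratify_by_zoom(rel, z_min, z_max)
  pos <- layout_base(g, seed = seed)
  split <- split_vertices(g, pos, d_max = d_max, relevance = rel)
  sc <- network_scene(g, split, strata, rel)
  deg <- igraph::degree(g)
  details <- stats::setNames(lapply(igraph::V(g)$name, function(v) {
    list(id = v, degree = unname(deg[v]),
         relevance = unname(rel$score[v]),
         interactors = sort(igraph::neighbors(g, v)$name))
  }), igraph::V(g)$name)
  manifests <- list(copies = export_copy_manifest(split),
                    strata = strata, details = details)
  list(relevance = rel, strata = strata, positions = pos, split = split,
       scene = sc, manifests = manifests)
}
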