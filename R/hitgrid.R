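## Spatial-grid hit-test manifests: selectable geometry is exported split
## over a fixed G x G grid so a client fetches only the clicked cell's
## file, plus the reference hit-testing the client would perform.

#' Create a selectable element
#'
#' @param id Element id (unique within a manifest).
#' @param type `"point"`, `"polyline"` or `"rect"`.
#' @param coords For a point, `c(x, y)`; for a polyline, an `n x 2`
#'   matrix of vertices; for a rect, `c(x0, y0, x1, y1)`.
#' @param detail_ref Optional path of the element's detail record.
#' @return An object of class `gm_element`.
#' @export
selectable_element <- function(id, type = c("point", "polyline", "rect"),
                               coords, detail_ref = NULL) {
  type <- match.arg(type)
  if (type == "polyline") {
    coords <- as.matrix(coords)
    stopifnot(ncol(coords) == 2, nrow(coords) >= 2)
  } else if (type == "point") {
    stopifnot(length(coords) == 2)
  } else {
    stopifnot(length(coords) == 4)
    coords <- c(pmin(coords[c(1, 2)], coords[c(3, 4)]),
                pmax(coords[c(1, 2)], coords[c(3, 4)]))
  }
  structure(list(id = id, type = type, coords = coords,
                 detail_ref = detail_ref), class = "gm_element")
}

element_bbox <- function(el) {
  switch(el$type,
    point = c(el$coords[1], el$coords[2], el$coords[1], el$coords[2]),
    rect = el$coords,
    polyline = c(min(el$coords[, 1]), min(el$coords[, 2]),
                 max(el$coords[, 1]), max(el$coords[, 2])))
}

#' Exact distance from a point to an element's geometry
#'
#' Point-to-polyline distance is the minimum distance to any segment
#' (exact, not vertex-only); distance to a rectangle is zero inside it.
#'
#' @param px,py Query point.
#' @param el A `gm_element`.
#' @return Non-negative distance in world units.
#' @export
element_distance <- function(px, py, el) {
  switch(el$type,
    point = sqrt((px - el$coords[1])^2 + (py - el$coords[2])^2),
    rect = {
      dx <- pmax(el$coords[1] - px, 0, px - el$coords[3])
      dy <- pmax(el$coords[2] - py, 0, py - el$coords[4])
      sqrt(dx^2 + dy^2)
    },
    polyline = {
      v <- el$coords
      n <- nrow(v)
      ax <- v[-n, 1]; ay <- v[-n, 2]
      bx <- v[-1, 1]; by <- v[-1, 2]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      t <- ifelse(len2 > 0, ((px - ax) * vx + (py - ay) * vy) / len2, 0)
      t <- pmin(1, pmax(0, t))
      min(sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
    })
}

#' Build a spatial-grid manifest
#'
#' Partitions selectable elements over a `G x G` grid spanning the world:
#' an element is listed in every cell its bounding box intersects
#' (conservative, cheap; hit tests re-check exact distance). Optionally
#' writes one JSON file per non-empty cell plus the grid manifest, the
#' lazy-loading layout a client uses.
#'
#' @param elements List of [selectable_element()]s.
#' @param G Grid side (default 10).
#' @param out_dir If non-`NULL`, write per-cell files + `grid.json` here.
#' @return An object of class `gm_grid`: list with `G`, `cells` (named
#'   `"i_j"` with 0-based cell coordinates, each a list of elements),
#'   `files` (cell -> file name, when written), `out_dir`.
#' @export
build_grid <- function(elements, G = 10, out_dir = NULL) {
  if (G < 1) stop("G must be >= 1")
  ids <- vapply(elements, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate element ids")
  cells <- list()
  for (el in elements) {
    bb <- element_bbox(el)
    ix0 <- max(0L, min(G - 1L, floor(bb[1] * G)))
    ix1 <- max(0L, min(G - 1L, floor(bb[3] * G - 1e-12)))
    iy0 <- max(0L, min(G - 1L, floor(bb[2] * G)))
    iy1 <- max(0L, min(G - 1L, floor(bb[4] * G - 1e-12)))
    for (i in ix0:ix1) {
      for (j in iy0:iy1) {
        key <- paste0(i, "_", j)
        cells[[key]] <- c(cells[[key]], list(el))
      }
    }
  }
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- stats::setNames(character(length(cells)), names(cells))
    for (key in names(cells)) {
      fn <- paste0("cell_", key, ".json")
      files[[key]] <- fn
      jsonlite::write_json(
        list(elements = lapply(cells[[key]], function(el) {
          list(id = el$id, type = el$type,
               coords = if (is.matrix(el$coords)) {
                 apply(el$coords, 1, as.numeric, simplify = FALSE)
               } else as.numeric(el$coords),
               detail_ref = el$detail_ref)
        })),
        file.path(out_dir, fn), auto_unbox = TRUE, digits = NA, null = "null")
    }
    jsonlite::write_json(list(G = G, cells = as.list(files)),
                         file.path(out_dir, "grid.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(G = G, cells = cells, files = files, out_dir = out_dir),
            class = "gm_grid")
}

## Cell accessor with an access counter, mimicking the client's lazy
## per-cell file fetches; tests assert the locality bound on it.
grid_cell <- function(grid, i, j, counter = NULL) {
  key <- paste0(i, "_", j)
  if (!is.null(counter)) {
    counter$n <- counter$n + 1L
  }
  grid$cells[[key]]
}

#' Hit-test a point against a grid manifest
#'
#' Loads only the cells within `tolerance` of the click (the files a
#' client would fetch) and returns the element minimizing exact
#' point-to-geometry distance, provided it is within `tolerance`; ties are
#' broken by id. The result is identical to brute force over all
#' elements.
#'
#' @param px,py Click position in world coordinates.
#' @param grid A `gm_grid`.
#' @param tolerance Maximum hit distance in world units (default 0.01).
#' @param counter Optional environment with field `n`; incremented once
#'   per cell accessed (for verifying access locality).
#' @return The winning element id, or `NULL` on a miss.
#' @export
hit_test <- function(px, py, grid, tolerance = 0.01, counter = NULL) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  G <- grid$G
  i0 <- max(0L, min(G - 1L, floor((px - tolerance) * G)))
  i1 <- max(0L, min(G - 1L, floor((px + tolerance) * G)))
  j0 <- max(0L, min(G - 1L, floor((py - tolerance) * G)))
  j1 <- max(0L, min(G - 1L, floor((py + tolerance) * G)))
  best_id <- NULL
  best_d <- Inf
  seen <- character(0)
  for (i in i0:i1) {
    for (j in j0:j1) {
      for (el in grid_cell(grid, i, j, counter)) {
        if (el$id %in% seen) next
        seen <- c(seen, el$id)
        d <- element_distance(px, py, el)
        if (d < best_d - 1e-15 ||
            (abs(d - best_d) <= 1e-15 && !is.null(best_id) &&
             el$id < best_id)) {
          best_d <- d
          best_id <- el$id
        }
      }
    }
  }
  if (is.finite(best_d) && best_d <= tolerance) best_id else NULL
}

#' Rectangle selection against a grid manifest
#'
#' Returns the ids of elements fully enclosed by the rectangle (enclosure,
#' not mere intersection — users draw enclosing rectangles; pass
#' `mode = "intersect"` for the looser semantics), sorted by id. Identical
#' to brute force over all elements.
#'
#' @param rect `c(x0, y0, x1, y1)` world rectangle.
#' @param grid A `gm_grid`.
#' @param mode `"enclose"` (default) or `"intersect"`.
#' @return Character vector of element ids (possibly empty), sorted.
#' @export
rect_select <- function(rect, grid, mode = c("enclose", "intersect")) {
  mode <- match.arg(mode)
  rect <- c(pmin(rect[c(1, 2)], rect[c(3, 4)]),
            pmax(rect[c(1, 2)], rect[c(3, 4)]))
  G <- grid$G
  i0 <- max(0L, min(G - 1L, floor(rect[1] * G)))
  i1 <- max(0L, min(G - 1L, floor(rect[3] * G)))
  j0 <- max(0L, min(G - 1L, floor(rect[2] * G)))
  j1 <- max(0L, min(G - 1L, floor(rect[4] * G)))
  hits <- character(0)
  seen <- character(0)
  for (i in i0:i1) {
    for (j in j0:j1) {
      for (el in grid_cell(grid, i, j)) {
        if (el$id %in% seen) next
        seen <- c(seen, el$id)
        bb <- element_bbox(el)
        ok <- if (mode == "enclose") {
          bb[1] >= rect[1] && bb[2] >= rect[2] &&
            bb[3] <= rect[3] && bb[4] <= rect[4]
        } else {
          bb[1] <= rect[3] && bb[3] >= rect[1] &&
            bb[2] <= rect[4] && bb[4] >= rect[2]
        }
        if (ok) hits <- c(hits, el$id)
      }
    }
  }
  sort(hits)
}
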