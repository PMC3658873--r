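## Tile pyramid geometry, rendering and background-tile deduplication.

#' Define a tile pyramid
#'
#' A tile pyramid is a multi-resolution image set: zoom level `z` is a
#' `2^z x 2^z` grid of fixed-size tiles jointly depicting one scene, laid
#' out on disk in the XYZ slippy-map convention `{z}/{x}/{y}.png`.
#'
#' @param z_max Maximum zoom level (>= 0). Capped at 8 by default because
#'   deep pyramids quickly become infeasible to distribute (the tile count
#'   quadruples per level); raise `z_cap` deliberately if needed.
#' @param tile_size Tile edge in pixels (default 256).
#' @param world_extent Side of the square world mapped onto the zoom-0
#'   tile, in world units.
#' @param image_format Tile encoding; only lossless `"png"` is supported,
#'   as background-tile deduplication relies on exact pixel equality.
#' @param background Background fill color shared by all tiles.
#' @param z_cap Safety cap on `z_max`.
#' @return An object of class `gm_pyramid`.
#' @export
#' @examples
#' p <- tile_pyramid(z_max = 3)
#' pyramid_tile_count(p$z_max)
tile_pyramid <- function(z_max, tile_size = 256, world_extent = 1,
                         image_format = "png", background = "white",
                         z_cap = 8) {
  if (z_max < 0) stop("z_max must be >= 0")
  if (z_max > z_cap) {
    stop("z_max = ", z_max, " exceeds the cap (", z_cap,
         "); deep pyramids are infeasible to distribute. ",
         "Raise z_cap explicitly if you really want this.")
  }
  if (!identical(image_format, "png")) {
    stop("only the lossless 'png' format is supported")
  }
  structure(list(z_max = as.integer(z_max), tile_size = as.integer(tile_size),
                 world_extent = world_extent, image_format = image_format,
                 background = background),
            class = "gm_pyramid")
}

#' Tiles per side at a zoom level
#'
#' @param z Zoom level (>= 0).
#' @return `2^z`, the number of tile columns (= rows) at zoom `z`.
#' @export
#' @examples
#' grid_side(3)  # 8
grid_side <- function(z) {
  if (any(z < 0)) stop("zoom level must be >= 0")
  as.integer(2^z)
}

#' Total tile slots in a pyramid
#'
#' The tile count quadruples with each zoom level, so a pyramid with
#' levels `0..z_max` holds `sum(4^(0:z_max))` slots.
#'
#' @param z_max Maximum zoom level (>= 0).
#' @return Integer total number of tile slots.
#' @export
#' @examples
#' pyramid_tile_count(8)  # 87381
pyramid_tile_count <- function(z_max) {
  if (any(z_max < 0)) stop("z_max must be >= 0")
  sum(4^(0:z_max))
}

#' Map a world point to its tile address and within-tile offset
#'
#' @param nx,ny Normalized world coordinates in `[0, 1)`.
#' @param z Zoom level.
#' @param tile_size Tile edge in pixels.
#' @return List with `z`, `x`, `y` (tile address, half-open convention) and
#'   `ox`, `oy` (pixel offset within the tile).
#' @export
point_to_tile <- function(nx, ny, z, tile_size = 256) {
  if (nx < 0 || nx >= 1 || ny < 0 || ny >= 1) {
    stop("normalized coordinates must lie in [0, 1)")
  }
  n <- 2^z
  tx <- floor(nx * n)
  ty <- floor(ny * n)
  list(z = as.integer(z), x = as.integer(tx), y = as.integer(ty),
       ox = (nx * n - tx) * tile_size,
       oy = (ny * n - ty) * tile_size)
}

#' Inverse of [point_to_tile()]
#'
#' @param z,x,y Tile address.
#' @param ox,oy Pixel offset within the tile.
#' @param tile_size Tile edge in pixels.
#' @return Numeric `c(nx, ny)` world coordinates.
#' @export
tile_to_point <- function(z, x, y, ox = 0, oy = 0, tile_size = 256) {
  n <- 2^z
  c((x + ox / tile_size) / n, (y + oy / tile_size) / n)
}

tile_path <- function(out_dir, z, x, y, ext = "png") {
  file.path(out_dir, z, x, paste0(y, ".", ext))
}

#' Render a monolithic zoom-level raster
#'
#' Renders the full `tile_size * 2^z` square raster of a scene at one zoom
#' level (or a sub-block of it). Mainly useful for verifying the mosaic
#' property against tiled output.
#'
#' @param sc A [scene()].
#' @param pyramid A [tile_pyramid()].
#' @param z Zoom level.
#' @param quantize Snap values to the 8-bit grid PNG files use, so the
#'   result is comparable with tiles read back from disk.
#' @return Numeric array `side x side x 3`.
#' @export
render_raster <- function(sc, pyramid, z, quantize = TRUE) {
  side <- pyramid$tile_size * grid_side(z)
  img <- rasterize_region(sc, z, pyramid$tile_size, 0, 0, side, side)
  if (quantize) quantize8(img) else img
}

#' Render a scene into a tile pyramid on disk
#'
#' Writes one PNG file per tile slot, named `{out_dir}/{z}/{x}/{y}.png`.
#' Mosaicking all zoom-z tiles reproduces the zoom-z raster bit-exactly.
#'
#' @param sc A [scene()].
#' @param pyramid A [tile_pyramid()].
#' @param out_dir Output directory (created if missing).
#' @param progress_every Emit a progress message every this many tiles
#'   (0 = silent).
#' @return Invisibly, the number of tile files written.
#' @export
render_pyramid <- function(sc, pyramid, out_dir, progress_every = 500) {
  stopifnot(inherits(sc, "gm_scene"), inherits(pyramid, "gm_pyramid"))
  ts <- pyramid$tile_size
  n_done <- 0L
  for (z in 0:pyramid$z_max) {
    n <- grid_side(z)
    for (x in 0:(n - 1)) {
      dir.create(file.path(out_dir, z, x), recursive = TRUE,
                 showWarnings = FALSE)
      for (y in 0:(n - 1)) {
        img <- tryCatch(
          rasterize_region(sc, z, ts, x * ts, y * ts, ts, ts),
          error = function(e) {
            stop("scene draw failed at tile z=", z, " x=", x, " y=", y,
                 ": ", conditionMessage(e))
          })
        png::writePNG(img, tile_path(out_dir, z, x, y))
        n_done <- n_done + 1L
        if (progress_every > 0 && n_done %% progress_every == 0L) {
          message("rendered ", n_done, " tiles")
        }
      }
    }
  }
  invisible(n_done)
}

#' Assemble the zoom-z mosaic from a tile directory
#'
#' @param tile_dir Directory holding `{z}/{x}/{y}.png` tiles.
#' @param pyramid The pyramid the tiles belong to.
#' @param z Zoom level to assemble.
#' @return Numeric array `side x side x 3`.
#' @export
mosaic_tiles <- function(tile_dir, pyramid, z) {
  ts <- pyramid$tile_size
  n <- grid_side(z)
  side <- ts * n
  img <- array(0, dim = c(side, side, 3))
  for (x in 0:(n - 1)) {
    for (y in 0:(n - 1)) {
      path <- tile_path(tile_dir, z, x, y)
      if (!file.exists(path)) stop("missing tile: ", path)
      t <- png::readPNG(path)
      if (length(dim(t)) == 2) t <- array(rep(t, 3), dim = c(dim(t), 3))
      img[y * ts + 1:ts, x * ts + 1:ts, ] <- t[, , 1:3]
    }
  }
  img
}

background_tile_array <- function(pyramid) {
  ts <- pyramid$tile_size
  quantize8(array(rep(gm_rgb(pyramid$background), each = ts * ts),
                  dim = c(ts, ts, 3)))
}

#' Deduplicate background tiles
#'
#' Many tiles in a rendered pyramid show nothing but uniform background.
#' This pass deletes every tile that is pixel-identical to the pure
#' background tile, stores one shared copy as `background.png`, and exports
#' the covered tile coordinates so a client (or [reconstruct_tiles()]) can
#' substitute the shared tile for the missing slots.
#'
#' @param tile_dir Directory holding a complete rendered pyramid.
#' @param pyramid The pyramid that was rendered.
#' @param tolerance Maximum absolute per-channel deviation from the
#'   background tile still considered "empty". The default 0 requires exact
#'   pixel equality (the only safe choice for lossless tiles).
#' @return The deduplication manifest: a list with `background_tile` (path)
#'   and `addresses` (list of `c(z, x, y)`), also written to
#'   `dedup.json` inside `tile_dir`.
#' @export
deduplicate_tiles <- function(tile_dir, pyramid, tolerance = 0) {
  stopifnot(inherits(pyramid, "gm_pyramid"))
  bg <- background_tile_array(pyramid)
  addresses <- list()
  for (z in 0:pyramid$z_max) {
    n <- grid_side(z)
    for (x in 0:(n - 1)) {
      for (y in 0:(n - 1)) {
        path <- tile_path(tile_dir, z, x, y)
        if (!file.exists(path)) {
          stop("incomplete pyramid: missing tile ", path)
        }
        t <- png::readPNG(path)
        same <- length(dim(t)) == 3 && all(dim(t) == dim(bg)) &&
          max(abs(t - bg)) <= tolerance
        if (same) {
          addresses[[length(addresses) + 1L]] <- c(z, x, y)
          unlink(path)
        }
      }
    }
  }
  bg_path <- file.path(tile_dir, "background.png")
  png::writePNG(bg, bg_path)
  manifest <- list(background_tile = "background.png", addresses = addresses)
  jsonlite::write_json(manifest, file.path(tile_dir, "dedup.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Restore deduplicated tiles
#'
#' Copies the shared background tile back into every slot listed in the
#' dedup manifest, reconstructing the complete pyramid exactly.
#'
#' @param tile_dir Tile directory holding `dedup.json` and
#'   `background.png`.
#' @return Invisibly, the number of tiles restored.
#' @export
reconstruct_tiles <- function(tile_dir) {
  mf <- jsonlite::read_json(file.path(tile_dir, "dedup.json"),
                            simplifyVector = TRUE)
  bg_path <- file.path(tile_dir, mf$background_tile)
  addrs <- mf$addresses
  if (is.data.frame(addrs)) addrs <- as.matrix(addrs)
  if (is.list(addrs)) addrs <- do.call(rbind, addrs)
  k <- 0L
  if (length(addrs)) {
    for (i in seq_len(nrow(addrs))) {
      dest <- tile_path(tile_dir, addrs[i, 1], addrs[i, 2], addrs[i, 3])
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      file.copy(bg_path, dest, overwrite = TRUE)
      k <- k + 1L
    }
  }
  invisible(k)
}
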