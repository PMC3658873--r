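## Primitive rasterization engine.
##
## Scenes are lists of vector primitives in normalized world coordinates
## ([0,1)^2, origin top-left, y downward). Rasterization is pixel-center
## sampled: the color of a pixel depends only on its global pixel index and
## the primitive list, never on the viewport it is rendered through. This is
## what makes the tile mosaic bit-identical to a monolithic render.

#' Convert an R color to a numeric RGB triple
#'
#' @param col Any color accepted by [grDevices::col2rgb()].
#' @return Numeric vector of length 3 in `[0, 1]`.
#' @keywords internal
#' @noRd
gm_rgb <- function(col) {
  as.numeric(grDevices::col2rgb(col)) / 255
}

new_prim <- function(type, ...) {
  structure(list(type = type, ...), class = "gm_prim")
}

#' Scene primitives
#'
#' Constructors for the drawing primitives understood by the rasterizer.
#' All coordinates are normalized world coordinates; widths and radii are
#' in world units. `alpha` blends the primitive over what is already drawn
#' (source-over).
#'
#' @param x0,y0,x1,y1 Rectangle corners or segment endpoints.
#' @param col Fill color.
#' @param alpha Opacity in `[0, 1]`.
#' @name primitives
#' @return A primitive object for use in [scene()].
NULL

#' @rdname primitives
#' @export
prim_rect <- function(x0, y0, x1, y1, col, alpha = 1) {
  new_prim("rect", x0 = min(x0, x1), y0 = min(y0, y1),
           x1 = max(x0, x1), y1 = max(y0, y1),
           col = gm_rgb(col), alpha = alpha)
}

#' @rdname primitives
#' @param cx,cy Disc center.
#' @param r Radius (world units).
#' @export
prim_disc <- function(cx, cy, r, col, alpha = 1) {
  stopifnot(r >= 0)
  new_prim("disc", cx = cx, cy = cy, r = r, col = gm_rgb(col), alpha = alpha)
}

#' @rdname primitives
#' @param lwd Full stroke width in world units.
#' @export
prim_segment <- function(x0, y0, x1, y1, lwd, col, alpha = 1) {
  new_prim("segment", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
           hw = lwd / 2, col = gm_rgb(col), alpha = alpha)
}

#' @rdname primitives
#' @param x,y Polyline vertex coordinate vectors.
#' @param closed Close the polyline back to its first vertex?
#' @export
prim_polyline <- function(x, y, lwd, col, alpha = 1, closed = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (closed) {
    x <- c(x, x[1])
    y <- c(y, y[1])
  }
  new_prim("polyline", x = x, y = y, hw = lwd / 2,
           col = gm_rgb(col), alpha = alpha)
}

#' @rdname primitives
#' @param colors Array `n_rows x n_cols x 3` of cell RGB values in `[0,1]`.
#' @param border_min_px Cell borders are drawn only when the on-screen cell
#'   width is at least this many pixels.
#' @param border_col Border color.
#' @export
prim_cellgrid <- function(x0, y0, x1, y1, colors, border_min_px = 4,
                          border_col = "grey25") {
  stopifnot(length(dim(colors)) == 3, dim(colors)[3] == 3)
  new_prim("cellgrid", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
           colors = colors, border_min_px = border_min_px,
           border_col = gm_rgb(border_col))
}

#' @rdname primitives
#' @param peak Peak (center) opacity of the radial glow.
#' @export
prim_glow <- function(cx, cy, r, peak, col) {
  stopifnot(r > 0, peak >= 0, peak <= 1)
  new_prim("glow", cx = cx, cy = cy, r = r, peak = peak, col = gm_rgb(col))
}

#' Create a drawable scene
#'
#' A scene couples a primitive list (or a zoom-indexed generator of one)
#' with a background color. Scenes satisfy render locality: drawing the
#' full zoom-z raster and cropping equals drawing the crop directly,
#' because every pixel is sampled at its center independently of the
#' viewport.
#'
#' @param primitives A list of primitives, or a `function(z)` returning one
#'   (semantic zoom: the displayed content may change with zoom level).
#' @param background Background fill color.
#' @return An object of class `gm_scene`.
#' @export
#' @examples
#' sc <- scene(list(prim_rect(0, 0, 0.5, 0.5, "red")), background = "white")
scene <- function(primitives, background = "white") {
  stopifnot(is.list(primitives) || is.function(primitives))
  structure(list(primitives = primitives, background = gm_rgb(background)),
            class = "gm_scene")
}

scene_prims <- function(scene, z) {
  p <- scene$primitives
  if (is.function(p)) p(z) else p
}

## Blend a color into img over a logical/numeric alpha mask covering the
## sub-block img[iy, ix, ].
blend_block <- function(img, iy, ix, amask, colv) {
  if (length(iy) == 0L || length(ix) == 0L) return(img)
  for (ch in 1:3) {
    old <- img[iy, ix, ch]
    img[iy, ix, ch] <- colv[ch] * amask + old * (1 - amask)
  }
  img
}

## Pixel-center world coordinates for global pixel indices px0..px0+n-1 at
## zoom z. side_px is the full raster side in pixels.
pixel_centers <- function(px0, n, side_px) {
  (px0 + seq_len(n) - 0.5) / side_px
}

#' Rasterize a scene region
#'
#' Renders the axis-aligned pixel block `[px_x0, px_x0 + w) x
#' [px_y0, px_y0 + h)` of the zoom-`z` raster (whose full side is
#' `tile_size * 2^z` pixels).
#'
#' @param sc A [scene()].
#' @param z Zoom level.
#' @param tile_size Tile edge in pixels.
#' @param px_x0,px_y0 Top-left global pixel coordinates of the block.
#' @param w,h Block width and height in pixels.
#' @return Numeric array `h x w x 3` with values in `[0, 1]`.
#' @export
rasterize_region <- function(sc, z, tile_size, px_x0, px_y0, w, h) {
  stopifnot(inherits(sc, "gm_scene"), z >= 0)
  side_px <- tile_size * 2^z
  xs <- pixel_centers(px_x0, w, side_px)
  ys <- pixel_centers(px_y0, h, side_px)
  img <- array(rep(sc$background, each = h * w), dim = c(h, w, 3))
  for (p in scene_prims(sc, z)) {
    img <- draw_prim(img, p, xs, ys, side_px)
  }
  img
}

draw_prim <- function(img, p, xs, ys, side_px) {
  switch(p$type,
    rect = {
      ix <- which(xs >= p$x0 & xs < p$x1)
      iy <- which(ys >= p$y0 & ys < p$y1)
      blend_block(img, iy, ix, p$alpha, p$col)
    },
    disc = {
      ix <- which(xs >= p$cx - p$r & xs <= p$cx + p$r)
      iy <- which(ys >= p$cy - p$r & ys <= p$cy + p$r)
      if (length(ix) && length(iy)) {
        d2 <- outer((ys[iy] - p$cy)^2, (xs[ix] - p$cx)^2, "+")
        mask <- (d2 <= p$r^2) * p$alpha
        img <- blend_block(img, iy, ix, mask, p$col)
      }
      img
    },
    segment = draw_segment(img, p$x0, p$y0, p$x1, p$y1, p$hw, p$col,
                           p$alpha, xs, ys),
    polyline = {
      n <- length(p$x)
      for (i in seq_len(n - 1)) {
        img <- draw_segment(img, p$x[i], p$y[i], p$x[i + 1], p$y[i + 1],
                            p$hw, p$col, p$alpha, xs, ys)
      }
      img
    },
    cellgrid = draw_cellgrid(img, p, xs, ys, side_px),
    glow = {
      ix <- which(xs >= p$cx - p$r & xs <= p$cx + p$r)
      iy <- which(ys >= p$cy - p$r & ys <= p$cy + p$r)
      if (length(ix) && length(iy)) {
        d <- sqrt(outer((ys[iy] - p$cy)^2, (xs[ix] - p$cx)^2, "+"))
        amask <- p$peak * pmax(0, 1 - d / p$r)
        img <- blend_block(img, iy, ix, amask, p$col)
      }
      img
    },
    stop("unknown primitive type: ", p$type)
  )
}

draw_segment <- function(img, x0, y0, x1, y1, hw, colv, alpha, xs, ys) {
  lo_x <- min(x0, x1) - hw; hi_x <- max(x0, x1) + hw
  lo_y <- min(y0, y1) - hw; hi_y <- max(y0, y1) + hw
  ix <- which(xs >= lo_x & xs <= hi_x)
  iy <- which(ys >= lo_y & ys <= hi_y)
  if (!length(ix) || !length(iy)) return(img)
  px <- matrix(xs[ix], nrow = length(iy), ncol = length(ix), byrow = TRUE)
  py <- matrix(ys[iy], nrow = length(iy), ncol = length(ix))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    d2 <- (px - x0)^2 + (py - y0)^2
  } else {
    t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
    d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  }
  blend_block(img, iy, ix, (d2 <= hw^2) * alpha, colv)
}

draw_cellgrid <- function(img, p, xs, ys, side_px) {
  nr <- dim(p$colors)[1]; nc <- dim(p$colors)[2]
  cw <- (p$x1 - p$x0) / nc
  chh <- (p$y1 - p$y0) / nr
  ix <- which(xs >= p$x0 & xs < p$x1)
  iy <- which(ys >= p$y0 & ys < p$y1)
  if (!length(ix) || !length(iy)) return(img)
  fx <- (xs[ix] - p$x0) / cw   # fractional column position
  fy <- (ys[iy] - p$y0) / chh
  jx <- pmin(nc, floor(fx) + 1L)
  jy <- pmin(nr, floor(fy) + 1L)
  for (ch in 1:3) {
    cm <- p$colors[, , ch, drop = FALSE]
    dim(cm) <- c(nr, nc)
    img[iy, ix, ch] <- cm[cbind(rep(jy, times = length(jx)),
                                rep(jx, each = length(jy)))]
  }
  # borders only when cells are wide enough on screen to afford them
  cw_px <- cw * side_px
  ch_px <- chh * side_px
  if (min(cw_px, ch_px) >= p$border_min_px) {
    offx <- (fx - floor(fx)) * cw_px
    offy <- (fy - floor(fy)) * ch_px
    bx <- offx < 0.5 | offx >= cw_px - 0.5
    by <- offy < 0.5 | offy >= ch_px - 0.5
    bmask <- outer(by, bx, "|") * 1
    img <- blend_block(img, iy, ix, bmask, p$border_col)
  }
  img
}

## Quantize to the 8-bit grid the PNG writer uses, staying on the [0,1]
## scale readPNG returns. Keeps in-memory renders comparable bit-for-bit
## with tiles that went through a PNG round trip.
quantize8 <- function(img) {
  round(pmin(pmax(img, 0), 1) * 255) / 255
}
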