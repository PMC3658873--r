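## Site builder: ties readers, builders, tilers and manifest writers into
## reproducible static-site builds, plus the fixture emitter. One viewer
## per invocation; a build re-run from its recorded config is
## byte-identical.

#' Build configuration
#'
#' @param kind Viewer kind: `"coexpr"`, `"heatmap"`, `"genome"`,
#'   `"network"` or `"tracts"`.
#' @param inputs Named list of input paths (`matrix`, `edges`, `bed`,
#'   `tracts`, `highlight`, ... depending on the kind).
#' @param out Output site directory.
#' @param tile_size,z_max,background Tile parameters.
#' @param params Viewer-specific parameters (`alpha`, `d_max`, `k`,
#'   `min_width`, `grid_G`, `glyph_zoom`, `cluster`).
#' @param seed RNG seed for every stochastic step of the build.
#' @param dedup Run background-tile deduplication after rendering?
#' @return A list of class `gm_config`.
#' @export
build_config <- function(kind, inputs, out, tile_size = 256, z_max = 4,
                         background = "white", params = list(), seed = 1,
                         dedup = TRUE) {
  kind <- match.arg(kind, c("coexpr", "heatmap", "genome", "network",
                            "tracts"))
  defaults <- list(alpha = 0.3, d_max = 0.15, k = 3, min_width = 8,
                   grid_G = 10, glyph_zoom = 3, cluster = TRUE)
  params <- utils::modifyList(defaults, params)
  structure(list(kind = kind, inputs = inputs, out = out,
                 tile_size = tile_size, z_max = z_max,
                 background = background, params = params, seed = seed,
                 dedup = dedup),
            class = "gm_config")
}

#' Read a build config from JSON
#' @param path JSON config file.
#' @return A `gm_config`.
#' @export
read_build_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$params <- as.list(cfg$params)
  cfg$inputs <- as.list(cfg$inputs)
  do.call(build_config, cfg[intersect(names(cfg), names(formals(build_config)))])
}

write_manifest <- function(obj, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
}

#' Build a static visualization site
#'
#' Runs the full offline pipeline for one viewer: read inputs, compute the
#' layout, render the tile pyramid(s), deduplicate background tiles,
#' export all interaction manifests and per-element detail files, write a
#' minimal static viewer page, the resolved config (`build.json`) and a
#' build log. The resulting directory can be served by copying it onto any
#' web server; no server-side computation is needed.
#'
#' @param config A [build_config()].
#' @return The site directory path, invisibly.
#' @export
build_site <- function(config) {
  stopifnot(inherits(config, "gm_config"))
  for (p in config$inputs) {
    if (is.character(p) && !file.exists(p)) {
      stop("input not found: ", p, " (", config$kind, " build)")
    }
  }
  site <- config$out
  dir.create(site, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(site, "INCOMPLETE")
  file.create(marker)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  ok <- FALSE
  on.exit({
    if (ok) unlink(marker)
    writeLines(log_lines, file.path(site, "build.log"))
  }, add = TRUE)

  pyr <- tile_pyramid(z_max = config$z_max, tile_size = config$tile_size,
                      background = config$background)
  pr <- config$params
  say("building ", config$kind, " site at ", site)

  tiles_dir <- file.path(site, "tiles")
  man_dir <- file.path(site, "manifests")
  det_dir <- file.path(site, "details")
  dir.create(det_dir, recursive = TRUE, showWarnings = FALSE)

  n_tiles <- 0L
  render_and_dedup <- function(sc, dir) {
    n <- render_pyramid(sc, pyr, dir)
    say("rendered ", n, " tiles into ", dir)
    if (config$dedup) {
      mf <- deduplicate_tiles(dir, pyr)
      say("deduplicated ", length(mf$addresses), " background tiles")
    }
    n
  }

  elements <- list()
  if (config$kind == "heatmap") {
    m <- read_expression_matrix(config$inputs$matrix)
    hb <- build_heatmap(m, 0, pyr$z_max, cluster = isTRUE(pr$cluster),
                        tile_size = pyr$tile_size)
    n_tiles <- render_and_dedup(hb$scene, tiles_dir)
    write_manifest(hb$manifests$axis_labels, man_dir, "axis_labels")
    write_manifest(hb$manifests$cell_lookup, man_dir, "cell_lookup")
  } else if (config$kind == "coexpr") {
    m <- read_expression_matrix(config$inputs$matrix)
    cb <- build_coexpr(m, 0, pyr$z_max, glyph_zoom = pr$glyph_zoom)
    n_tiles <- render_and_dedup(cb$scene, tiles_dir)
    for (nm in names(cb$manifests)) {
      write_manifest(cb$manifests[[nm]], man_dir, nm)
    }
    pos <- cb$embedding$positions
    elements <- lapply(rownames(pos), function(gid) {
      ref <- file.path("details", paste0(gid, ".json"))
      write_manifest(list(id = gid,
                          profile = as.numeric(m[gid, ]),
                          conditions = colnames(m)),
                     det_dir, gid)
      selectable_element(gid, "point", unname(pos[gid, ]), detail_ref = ref)
    })
  } else if (config$kind == "genome") {
    ann <- read_gene_annotations(config$inputs$bed)
    expr <- if (!is.null(config$inputs$matrix)) {
      read_expression_matrix(config$inputs$matrix)
    } else NULL
    highlight <- if (!is.null(config$inputs$highlight)) {
      readLines(config$inputs$highlight)
    } else NULL
    gb <- build_genome(ann, expr = expr, pyramid = pyr,
                       min_width = pr$min_width, highlight = highlight)
    n_tiles <- render_and_dedup(gb$scene, tiles_dir)
    write_manifest(gb$manifests$anchors, man_dir, "anchors")
    write_manifest(gb$manifests$label_min_zoom, man_dir, "label_min_zoom")
    write_manifest(gb$manifests$chromosomes, man_dir, "chromosomes")
    g <- gb$layout$genes
    elements <- lapply(seq_len(nrow(g)), function(i) {
      gid <- g$gene_id[i]
      ref <- file.path("details", paste0(gid, ".json"))
      write_manifest(list(id = gid, chrom = g$chrom[i],
                          strand = g$strand[i],
                          anchor = c(g$anchor_x[i], g$y_axis[i])),
                     det_dir, gid)
      selectable_element(gid, "rect",
                         c(g$disp_x0[i], g$band_y0[i], g$disp_x1[i],
                           g$band_y1[i]), detail_ref = ref)
    })
  } else if (config$kind == "network") {
    g <- read_interaction_graph(config$inputs$edges)
    nb <- build_network(g, 0, pyr$z_max, alpha = pr$alpha,
                        d_max = pr$d_max, seed = config$seed)
    n_tiles <- render_and_dedup(nb$scene, tiles_dir)
    write_manifest(nb$manifests$copies, man_dir, "copies")
    write_manifest(nb$manifests$strata, man_dir, "strata")
    for (v in names(nb$manifests$details)) {
      write_manifest(nb$manifests$details[[v]], det_dir, v)
    }
    cp <- nb$split$copies
    elements <- lapply(seq_len(nrow(cp)), function(i) {
      ref <- file.path("details", paste0(cp$canonical[i], ".json"))
      selectable_element(cp$copy_id[i], "point",
                         c(cp$x[i], cp$y[i]), detail_ref = ref)
    })
  } else if (config$kind == "tracts") {
    tracts <- read_tracts(config$inputs$tracts)
    tb <- build_tracts(tracts, k = pr$k)
    for (pl in names(tb$scenes)) {
      n_tiles <- n_tiles + render_and_dedup(tb$scenes[[pl]],
                                            file.path(tiles_dir, pl))
    }
    for (i in seq_along(tb$manifests$details)) {
      write_manifest(tb$manifests$details[[i]], det_dir,
                     paste0("cluster_", i))
    }
    # selectable geometry: centroid polylines on the transverse plane
    pr3 <- tb$projections$transverse
    elements <- lapply(seq_along(pr3$centroids), function(i) {
      selectable_element(paste0("cluster_", i), "polyline",
                         pr3$centroids[[i]],
                         detail_ref = file.path(
                           "details", paste0("cluster_", i, ".json")))
    })
  }

  if (length(elements)) {
    build_grid(elements, G = pr$grid_G, out_dir = file.path(site, "grid"))
    say("exported hit grid (G=", pr$grid_G, ") for ", length(elements),
        " selectable elements")
  }

  viewer_html(config, file.path(site, "viewer.html"))
  cfg_out <- unclass(config)
  jsonlite::write_json(cfg_out, file.path(site, "build.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("wrote ", n_tiles, " tiles total; build complete")
  ok <- TRUE
  invisible(site)
}

## Minimal static viewer page, generated from the shipped template and
## treated as data (kept single-language: no client code is authored here
## beyond wiring the tile directory into a generic pan-and-zoom widget).
viewer_html <- function(config, path) {
  tpl <- system.file("templates", "viewer.html", package = "genomaps")
  html <- paste(readLines(tpl), collapse = "\n")
  html <- gsub("{{KIND}}", config$kind, html, fixed = TRUE)
  html <- gsub("{{Z_MAX}}", config$z_max, html, fixed = TRUE)
  html <- gsub("{{TILE_SIZE}}", config$tile_size, html, fixed = TRUE)
  writeLines(html, path)
  invisible(path)
}

#' Emit synthetic fixture input files
#'
#' Writes the on-disk input files for one viewer kind (plus a labels
#' sidecar recording the generator's ground truth and seed).
#'
#' @param kind `"expression"`, `"graph"`, `"genome"` or `"tracts"`.
#' @param out Output directory.
#' @param seed Integer RNG seed.
#' @param ... Size/noise parameters forwarded to the matching
#'   `synth_*` generator.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(kind = c("expression", "graph", "genome",
                                   "tracts"),
                          out, seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  sidecar <- list(kind = kind, seed = seed)
  if (kind == "expression") {
    fx <- synth_expression(seed = seed, ...)
    files["matrix"] <- file.path(out, "expression.tsv")
    write_expression_tsv(fx$matrix, files["matrix"])
    sidecar$labels <- as.list(fx$labels)
  } else if (kind == "graph") {
    fx <- synth_graph(seed = seed, ...)
    files["edges"] <- file.path(out, "edges.tsv")
    write_edge_list(fx, files["edges"])
  } else if (kind == "genome") {
    fx <- synth_genome(seed = seed, expression = TRUE, ...)
    files["bed"] <- file.path(out, "genes.bed")
    write_bed(fx$annotations, files["bed"])
    files["matrix"] <- file.path(out, "expression.tsv")
    write_expression_tsv(fx$expression, files["matrix"])
    sidecar$chrom_lengths <- as.list(fx$chrom_lengths)
  } else {
    fx <- synth_tracts(seed = seed, ...)
    files["tracts"] <- file.path(out, "tracts.json")
    write_tract_json(fx$tracts, files["tracts"])
    sidecar$labels <- as.list(fx$labels)
  }
  jsonlite::write_json(sidecar, file.path(out, "labels.json"),
                       auto_unbox = TRUE, digits = NA)
  files["labels"] <- file.path(out, "labels.json")
  invisible(files)
}
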