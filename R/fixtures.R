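## Deterministic synthetic-data generators for every input kind the
## viewers consume, with planted structure and ground-truth labels. All
## randomness flows through one seeded RNG per generator; identical
## arguments give byte-identical outputs.

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  code
}

#' Synthetic expression matrix with planted clusters
#'
#' Each cluster gets a distinct random template profile (standard normal
#' draws, so templates are near-orthogonal in shape); member genes are the
#' template plus i.i.d. Gaussian noise. Cluster sizes are as equal as
#' possible.
#'
#' @param n_genes,n_conditions Matrix dimensions.
#' @param n_clusters Number of planted clusters (`<= n_genes`).
#' @param noise_sd Member noise standard deviation (same units as the
#'   templates; 0 = identical members).
#' @param seed Integer RNG seed.
#' @return List with `matrix` (rownames gene ids, colnames condition ids)
#'   and `labels` (named integer vector of planted cluster ids).
#' @export
synth_expression <- function(n_genes = 300, n_conditions = 24,
                             n_clusters = 3, noise_sd = 0.1, seed = 1) {
  if (n_clusters > n_genes || n_clusters < 1) {
    stop("need 1 <= n_clusters <= n_genes")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    templates <- matrix(stats::rnorm(n_clusters * n_conditions),
                        n_clusters, n_conditions)
    labels <- rep(seq_len(n_clusters), length.out = n_genes)
    labels <- sort(labels)
    m <- templates[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_conditions, sd = noise_sd),
             n_genes, n_conditions)
    ids <- sprintf("gene_%04d", seq_len(n_genes))
    dimnames(m) <- list(ids, sprintf("cond_%02d", seq_len(n_conditions)))
    list(matrix = m, labels = stats::setNames(labels, ids))
  })
}

#' Synthetic preferential-attachment interaction graph
#'
#' Standard Barabasi-Albert construction: `attachment_m` seed nodes with
#' no edges; every subsequent node attaches to `attachment_m` distinct
#' existing nodes chosen with probability proportional to degree (plus
#' one, so isolated seed nodes can be chosen). Simple, connected, with
#' `attachment_m * (n_nodes - attachment_m)` edges and a heavy-tailed
#' degree distribution.
#'
#' @param n_nodes Number of nodes (`> attachment_m`).
#' @param attachment_m Edges added per new node (`>= 1`).
#' @param seed Integer RNG seed.
#' @return An [igraph::igraph] with node names `P001`, `P002`, ...
#' @export
synth_graph <- function(n_nodes = 300, attachment_m = 2, seed = 1) {
  if (attachment_m < 1 || n_nodes <= attachment_m) {
    stop("need n_nodes > attachment_m >= 1")
  }
  with_seed(seed, {
    deg <- integer(n_nodes)
    from <- integer(0); to <- integer(0)
    for (v in (attachment_m + 1):n_nodes) {
      existing <- seq_len(v - 1)
      prob <- deg[existing] + 1
      targets <- sample(existing, attachment_m, prob = prob)
      from <- c(from, rep(v, attachment_m))
      to <- c(to, targets)
      deg[v] <- deg[v] + attachment_m
      deg[targets] <- deg[targets] + 1L
    }
    nm <- sprintf("P%03d", seq_len(n_nodes))
    igraph::graph_from_data_frame(
      data.frame(from = nm[from], to = nm[to]),
      directed = FALSE, vertices = data.frame(name = nm))
  })
}

#' Synthetic genome annotations with alternating gene density
#'
#' Genes are not uniformly distributed along chromosomes: each chromosome
#' holds one dense interval occupying 10% of its span into which
#' `dense_fraction` of its genes are packed; the remaining genes spread
#' near-uniformly over the rest. Genes never overlap within a chromosome.
#'
#' @param n_genes Total gene count.
#' @param n_chrom Number of chromosomes.
#' @param dense_fraction Fraction of each chromosome's genes placed in its
#'   dense interval (in `[0, 1]`).
#' @param gene_length Gene length in bp.
#' @param chrom_length Length of the longest chromosome in bp (subsequent
#'   chromosomes shrink linearly to half this).
#' @param seed Integer RNG seed.
#' @param expression Also generate a joined expression matrix?
#' @return List with `annotations` (data.frame: `chrom`, `start`, `end`,
#'   `strand`, `gene_id`; 0-based half-open), `chrom_lengths`, and
#'   optionally `expression`.
#' @export
synth_genome <- function(n_genes = 200, n_chrom = 4, dense_fraction = 0.5,
                         gene_length = 5000, chrom_length = 1e7, seed = 1,
                         expression = FALSE) {
  if (dense_fraction < 0 || dense_fraction > 1) {
    stop("dense_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    lens <- round(chrom_length * seq(1, 0.5, length.out = n_chrom))
    names(lens) <- as.character(seq_len(n_chrom))
    per <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
    rows <- list()
    gi <- 0L
    for (ci in seq_len(n_chrom)) {
      ng <- per[ci]
      if (ng == 0) next
      L <- lens[ci]
      n_dense <- round(dense_fraction * ng)
      n_sparse <- ng - n_dense
      dense_w <- round(0.1 * L)
      if (n_dense * gene_length > dense_w) {
        stop("cannot pack ", n_dense, " genes of ", gene_length,
             " bp into the dense interval (", dense_w, " bp) of chromosome ",
             ci)
      }
      d0 <- round(stats::runif(1, 0.2, 0.7) * (L - dense_w))
      place <- function(n, lo, hi) {
        # evenly spaced slots with jitter, non-overlapping by construction
        if (n == 0) return(integer(0))
        slot <- (hi - lo) / n
        if (slot < gene_length) stop("infeasible packing on chromosome ", ci)
        jit <- stats::runif(n, 0, slot - gene_length)
        round(lo + (seq_len(n) - 1) * slot + jit)
      }
      if (n_dense == 0) {
        starts <- place(ng, 0, L - gene_length)  # near-uniform spacing
      } else {
        starts_d <- place(n_dense, d0, d0 + dense_w)
        # sparse genes avoid the dense interval by splitting around it
        n_left <- round(n_sparse * d0 / (L - dense_w))
        n_right <- n_sparse - n_left
        starts_s <- c(place(n_left, 0, d0),
                      place(n_right, d0 + dense_w, L - gene_length))
        starts <- sort(c(starts_d, starts_s))
      }
      for (s in starts) {
        gi <- gi + 1L
        rows[[gi]] <- data.frame(
          chrom = as.character(ci), start = s, end = s + gene_length,
          strand = if (stats::runif(1) < 0.5) "+" else "-",
          gene_id = sprintf("gene_%04d", gi), stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)
    out <- list(annotations = ann, chrom_lengths = lens)
    if (expression) {
      ex <- synth_expression(n_genes = nrow(ann), n_conditions = 8,
                             n_clusters = 3, noise_sd = 0.3,
                             seed = seed + 1)
      rownames(ex$matrix) <- ann$gene_id
      out$expression <- ex$matrix
    }
    out
  })
}

#' Synthetic 3D tract bundles
#'
#' Each bundle is a smooth random template curve (a cubic-spline
#' interpolation of a few random control points); members are the template
#' plus a small random rigid offset and per-point jitter of scale
#' `spread`. Bundle origins are separated far relative to `spread`, so
#' bundles are recoverable ground truth.
#'
#' @param n_bundles Number of bundles.
#' @param tracts_per_bundle Members per bundle.
#' @param points_per_tract Points per curve.
#' @param spread Member jitter scale (same units as coordinates; 0 =
#'   members identical to the template).
#' @param seed Integer RNG seed.
#' @return List with `tracts` (list of `{id, points}`) and `labels`
#'   (named integer bundle ids).
#' @export
synth_tracts <- function(n_bundles = 3, tracts_per_bundle = 20,
                         points_per_tract = 30, spread = 0.5, seed = 1) {
  stopifnot(n_bundles >= 1, tracts_per_bundle >= 1, points_per_tract >= 2,
            spread >= 0)
  with_seed(seed, {
    tracts <- list()
    labels <- integer(0)
    tt <- seq(0, 1, length.out = points_per_tract)
    for (b in seq_len(n_bundles)) {
      origin <- c(20 * b, 10 * ((b %% 2) * 2 - 1), 5 * b)
      ctrl_t <- seq(0, 1, length.out = 5)
      ctrl <- matrix(stats::rnorm(15, sd = 4), 5, 3)
      template <- vapply(1:3, function(ax) {
        stats::spline(ctrl_t, origin[ax] + ctrl[, ax], xout = tt)$y
      }, numeric(points_per_tract))
      for (m in seq_len(tracts_per_bundle)) {
        offset <- stats::rnorm(3, sd = spread)
        jitter <- matrix(stats::rnorm(points_per_tract * 3,
                                      sd = spread / 4),
                         points_per_tract, 3)
        id <- sprintf("tract_%02d_%02d", b, m)
        tracts[[length(tracts) + 1L]] <-
          list(id = id,
               points = template +
                 matrix(offset, points_per_tract, 3, byrow = TRUE) + jitter)
        labels[id] <- b
      }
    }
    list(tracts = tracts, labels = labels)
  })
}

## ---- on-disk writers (the exact formats the consumer modules read) ----

#' Write an expression matrix as tab-delimited text
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as a two-column edge list
#' @param g An igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write annotations as BED6
#' @param ann Annotation data.frame (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0,
                    ann$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write tracts as JSON
#' @param tracts Tract list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tract_json <- function(tracts, path) {
  jsonlite::write_json(
    lapply(tracts, function(t) {
      list(id = t$id,
           points = apply(t$points, 1, as.numeric, simplify = FALSE))
    }),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
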