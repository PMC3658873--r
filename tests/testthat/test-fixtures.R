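# Synthetic generators: determinism, planted structure, loader round trips.

test_that("every generator is byte-deterministic per seed", {
  d1 <- tempfile(); d2 <- tempfile()
  for (kind in c("expression", "graph", "genome", "tracts")) {
    f1 <- make_fixtures(kind, file.path(d1, kind), seed = 5)
    f2 <- make_fixtures(kind, file.path(d2, kind), seed = 5)
    for (nm in names(f1)) {
      expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                       label = paste(kind, nm))
    }
  }
  unlink(d1, recursive = TRUE); unlink(d2, recursive = TRUE)
})

test_that("expression fixtures respect noise and cluster structure", {
  z <- synth_expression(12, 6, 3, noise_sd = 0, seed = 2)
  for (cl in 1:3) {
    rows <- z$matrix[z$labels == cl, ]
    expect_equal(expression_distance(rows[1, ], rows[2, ]), 0)
  }
  one <- synth_expression(10, 5, 1, noise_sd = 0.1, seed = 3)
  expect_true(all(one$labels == 1))
  expect_error(synth_expression(5, 4, 6, 0.1, 1), "n_clusters")
  expect_error(synth_expression(5, 4, 2, -1, 1), "noise_sd")

  # the flagship recovery case: 300 x 24, 3 clusters, sd 0.1
  fx <- synth_expression(300, 24, 3, noise_sd = 0.1, seed = 7)
  part <- stats::cutree(build_dendrogram(fx$matrix), k = 3)
  expect_gte(ari(part, fx$labels), 0.9)
})

test_that("preferential-attachment graphs have the closed-form edge count", {
  g <- synth_graph(2, 1, seed = 1)
  expect_equal(igraph::ecount(g), 1)
  for (par in list(c(50, 1), c(80, 2), c(120, 3))) {
    g <- synth_graph(par[1], par[2], seed = par[1])
    expect_equal(igraph::ecount(g), par[2] * (par[1] - par[2]))
    expect_true(igraph::is_connected(g))
    expect_false(igraph::any_multiple(g))
  }
  # heavy tail: hubs dominate the mean degree
  for (seed in 1:20) {
    g <- synth_graph(100, 2, seed = seed)
    deg <- igraph::degree(g)
    expect_gt(max(deg), 2 * mean(deg))
  }
  expect_error(synth_graph(3, 3, 1), "n_nodes")
})

test_that("genome fixtures alternate density and never overlap", {
  fx <- synth_genome(n_genes = 120, n_chrom = 3, dense_fraction = 0.8,
                     seed = 9)
  ann <- fx$annotations
  for (cc in unique(ann$chrom)) {
    a <- ann[ann$chrom == cc, ]
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] >= a$end[-nrow(a)]))  # no overlaps
    expect_true(all(a$end <= fx$chrom_lengths[[cc]]))
  }
  # a dense fixture forces the spreader to move glyphs
  ly <- spread_glyphs(layout_genome(ann, fx$chrom_lengths),
                      min_width = 8, pyramid = tile_pyramid(4))
  moved <- sum(abs(ly$genes$leader_from_x - ly$genes$leader_to_x) > 1e-12)
  expect_gte(moved, 1)
  # near-uniform fixture spreads genes over the whole chromosome
  u <- synth_genome(n_genes = 60, n_chrom = 1, dense_fraction = 0,
                    seed = 2)
  gaps <- diff(sort(u$annotations$start))
  expect_lt(max(gaps) / stats::median(gaps), 3)
})

test_that("tract bundles collapse at zero spread and separate otherwise", {
  z <- synth_tracts(2, 4, 12, spread = 0, seed = 3)
  d12 <- curve_distance(z$tracts[[1]], z$tracts[[2]])
  expect_lt(d12, 1e-5)
  one <- cluster_tracts(synth_tracts(1, 5, 10, 0.2, seed = 1)$tracts, 1)
  expect_equal(one[[1]]$stats$n, 5)
})

test_that("fixture files round-trip through the module loaders", {
  out <- tempfile()
  fe <- make_fixtures("expression", out, seed = 4, n_genes = 20,
                      n_conditions = 6)
  m <- read_expression_matrix(fe[["matrix"]])
  expect_equal(dim(m), c(20, 6))
  # text serialization keeps ~15 significant digits
  expect_equal(m, synth_expression(20, 6, seed = 4)$matrix,
               tolerance = 1e-12)

  fgra <- make_fixtures("graph", out, seed = 4, n_nodes = 30)
  g <- read_interaction_graph(fgra[["edges"]])
  expect_equal(igraph::vcount(g), 30)

  fgen <- make_fixtures("genome", out, seed = 4, n_genes = 25, n_chrom = 2)
  ann <- read_gene_annotations(fgen[["bed"]])
  orig <- synth_genome(n_genes = 25, n_chrom = 2, seed = 4)$annotations
  expect_equal(ann[order(ann$gene_id), c("chrom", "start", "end", "gene_id")],
               orig[order(orig$gene_id), c("chrom", "start", "end", "gene_id")],
               ignore_attr = TRUE)

  ftr <- make_fixtures("tracts", out, seed = 4, n_bundles = 2,
                       tracts_per_bundle = 3, points_per_tract = 8)
  tr <- read_tracts(ftr[["tracts"]])
  orig_tr <- synth_tracts(2, 3, 8, seed = 4)$tracts
  expect_equal(length(tr), 6)
  expect_equal(tr[[1]]$points, orig_tr[[1]]$points, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(out, recursive = TRUE)
})
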