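# Co-expression map: distances, dendrogram, zoom-linked cuts, embedding.

test_that("expression_distance is 1 - Pearson with the documented extremes", {
  a <- c(1, 2, 3)
  expect_equal(expression_distance(a, a), 0)
  expect_equal(expression_distance(a, -a + 10), 2)
  # hand-computed: cov = 1.5, sd_a = 1, sd_b = sqrt(7/3)
  expect_equal(expression_distance(c(1, 2, 3), c(1, 2, 4)),
               1 - 1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(1 - 1.5 / sqrt(7 / 3), 0.018019494, tolerance = 1e-8)
  expect_error(expression_distance(c(1, 1, 1), a), "constant")
  expect_equal(expression_distance(c(1, 1, 1), c(1, 2, 3),
                                   method = "euclidean"), sqrt(0 + 1 + 4))
})

test_that("build_dendrogram matches brute-force average-linkage on small cases", {
  # two genes: a single merge at their pairwise distance
  m2 <- matrix(c(1, 2, 3, 3, 1, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  t2 <- build_dendrogram(m2)
  expect_equal(t2$height, expression_distance(m2[1, ], m2[2, ]))

  # brute-force agglomeration oracle on 5 profiles
  m <- with_test_seed(3, matrix(rnorm(5 * 6), 5, 6,
                                dimnames = list(letters[1:5], NULL)))
  d <- as.matrix(expression_dist(m))
  clusters <- as.list(1:5)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(build_dendrogram(m)$height, heights, tolerance = 1e-12)
})

test_that("a planted low-noise 3-cluster fixture is recovered exactly", {
  fx <- synth_expression(n_genes = 90, n_conditions = 12, n_clusters = 3,
                         noise_sd = 0.05, seed = 7)
  part <- stats::cutree(build_dendrogram(fx$matrix), k = 3)
  expect_equal(ari(part, fx$labels), 1)
})

test_that("zoom-linked cuts are nested, refine with zoom, and start at the root", {
  fx <- synth_expression(n_genes = 60, n_conditions = 10, n_clusters = 3,
                         noise_sd = 0.1, seed = 2)
  tree <- build_dendrogram(fx$matrix)
  cuts <- cuts_for_zoom(tree, 0, 4)
  expect_length(cuts, 5)
  expect_equal(length(unique(cuts[[1]]$partition)), 1)  # root cut
  counts <- vapply(cuts, function(cc) length(unique(cc$partition)), 1)
  expect_true(all(diff(counts) >= 0))
  heights <- vapply(cuts, `[[`, numeric(1), "height")
  expect_true(all(diff(heights) < 0))
  # nesting: each finer cluster sits inside exactly one coarser cluster
  for (i in seq_len(length(cuts) - 1)) {
    coarse <- cuts[[i]]$partition
    fine <- cuts[[i + 1]]$partition
    expect_true(all(vapply(split(names(fine), fine), function(genes) {
      length(unique(coarse[genes])) == 1
    }, logical(1))))
  }
  # some zoom's cut recovers the planted 3 groups
  k3 <- Filter(function(cc) length(unique(cc$partition)) == 3, cuts)
  expect_gt(length(k3), 0)
  expect_equal(ari(k3[[1]]$partition, fx$labels), 1)
  # single-zoom range gives a single partition; degenerate 1-leaf tree works
  expect_length(cuts_for_zoom(tree, 2, 2), 1)
  single <- cuts_for_zoom(NULL, 0, 2, labels = "g1")
  expect_true(all(vapply(single, function(cc) {
    identical(cc$partition, stats::setNames(1L, "g1"))
  }, logical(1))))
})

test_that("embedding separates planted clusters in the plane", {
  for (seed in 1:20) {
    fx <- synth_expression(n_genes = 45, n_conditions = 8, n_clusters = 3,
                           noise_sd = 0.15, seed = seed)
    part <- stats::cutree(build_dendrogram(fx$matrix), k = 3)
    emb <- embed_genes(fx$matrix, part)
    pos <- emb$positions
    expect_true(all(pos >= 0 & pos < 1))
    dmat <- as.matrix(dist(pos))
    same <- outer(part, part, "==")
    diag(same) <- NA
    within <- mean(dmat[same & !is.na(same)])
    between <- mean(dmat[!same & !is.na(same)])
    expect_lt(within, between)
  }
})

test_that("identical centroids fall back to angular placement with disjoint discs", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1),
             c = c(1, 2, 3, 4), d = c(4, 3, 2, 1))
  part <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(m))
  expect_warning(emb <- embed_genes(m, part), "fallback|identical|angular")
  gap <- sqrt(sum((emb$centers[1, ] - emb$centers[2, ])^2))
  expect_gt(gap, sum(emb$radii))
  # single cluster: genes inside one disc around the world center
  emb1 <- embed_genes(m, stats::setNames(rep(1L, 4), rownames(m)))
  r <- sqrt(rowSums(sweep(emb1$positions, 2, emb1$centers[1, ])^2))
  expect_true(all(r <= emb1$radii[1]))
})

test_that("aggregate_profile is the mean with the weighted-mean identity", {
  expect_equal(aggregate_profile(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(aggregate_profile(rbind(c(0, 0, 0), c(2, 4, 6))), c(1, 2, 3))
  expect_error(aggregate_profile(matrix(0, 0, 3)), "empty")
  m <- with_test_seed(8, matrix(rnorm(30), 10, 3))
  part <- rep(1:3, length.out = 10)
  per <- vapply(1:3, function(cl) {
    aggregate_profile(m[part == cl, , drop = FALSE])
  }, numeric(3))
  sizes <- tabulate(part)
  expect_equal(as.numeric(per %*% sizes / sum(sizes)),
               as.numeric(aggregate_profile(m)))
  # permutation invariance
  o <- c(5, 2, 9, 1, 3, 10, 4, 8, 6, 7)
  expect_equal(aggregate_profile(m[o, ]), aggregate_profile(m))
})

test_that("the co-expression scene draws every gene and one glyph per cluster", {
  fx <- synth_expression(n_genes = 30, n_conditions = 6, n_clusters = 3,
                         noise_sd = 0.1, seed = 4)
  cb <- build_coexpr(fx$matrix, 0, 2, glyph_zoom = 2)
  prims0 <- genomaps:::scene_prims(cb$scene, 0)
  types0 <- vapply(prims0, `[[`, character(1), "type")
  # zoom 0: one cluster -> 1 boundary + 1 cluster glyph + 30 gene dots
  expect_equal(sum(types0 == "disc"), 30)
  expect_equal(sum(types0 == "cellgrid"),
               length(unique(cb$cuts[[1]]$partition)))
  # at the glyph zoom, genes switch from dots to per-gene strips
  prims2 <- genomaps:::scene_prims(cb$scene, 2)
  types2 <- vapply(prims2, `[[`, character(1), "type")
  n_clust2 <- length(unique(cb$cuts[[3]]$partition))
  expect_equal(sum(types2 == "disc"), 0)
  expect_equal(sum(types2 == "cellgrid"), 30 + n_clust2)
})
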