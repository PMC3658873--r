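# Network relevance, zoom stratification, layout, vertex splitting.

star5 <- function() {
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", "l1", "l2", "l3", "l4")
  g
}

test_that("relevance mixes intrinsic and diffused parts as documented", {
  s <- star5()
  # degrees as base: hub 4, leaves 1
  r5 <- compute_relevance(s, alpha = 0.5)
  expect_equal(unname(r5$raw), c(2.5, 2.5, 2.5, 2.5, 2.5))
  expect_equal(unname(r5$score), rep(1, 5))  # constant maps to 1
  r2 <- compute_relevance(s, alpha = 0.2)
  expect_equal(r2$raw[["hub"]], 0.8 * 4 + 0.2 * 1)  # 3.4
  expect_equal(r2$raw[["l1"]], 0.8 * 1 + 0.2 * 4)   # 1.6
  expect_equal(r2$score[["hub"]], 1)
  expect_equal(r2$score[["l1"]], 0)

  # alpha = 0 is pure intrinsic weight; alpha = 1 the neighborhood mean
  w <- c(hub = 10, l1 = 1, l2 = 2, l3 = 3, l4 = 4)
  r0 <- compute_relevance(s, alpha = 0, weights = w)
  expect_equal(r0$raw, w[names(r0$raw)])
  r1 <- compute_relevance(s, alpha = 1, weights = w)
  expect_equal(r1$raw[["hub"]], mean(1:4))
  expect_equal(r1$raw[["l2"]], 10)
  expect_error(compute_relevance(s, alpha = 1.5), "alpha")

  # isolated node keeps its own weight
  gi <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(gi)$name <- "solo"
  igraph::V(gi)$weight <- 7
  expect_equal(compute_relevance(gi, alpha = 0.9)$raw[["solo"]], 7)
})

test_that("zoom strata are nested, tie-respecting and complete at z_max", {
  for (seed in 1:5) {
    g <- synth_graph(80, 2, seed = seed)
    rel <- compute_relevance(g)
    st <- stratify_by_zoom(rel, 0, 4)
    for (z in 0:3) {
      expect_true(all(st[[as.character(z)]] %in% st[[as.character(z + 1)]]))
    }
    expect_setequal(st[["4"]], igraph::V(g)$name)
    # overview strata are genuinely sparser
    expect_lt(length(st[["0"]]), length(st[["4"]]))
  }
  # uniform scores: ties keep everything visible at every zoom
  s <- star5()
  st_u <- stratify_by_zoom(compute_relevance(s, alpha = 0.5), 0, 3)
  for (z in 0:3) expect_setequal(st_u[[as.character(z)]], igraph::V(s)$name)
  # single zoom level shows all nodes
  st1 <- stratify_by_zoom(compute_relevance(s, alpha = 0.2), 2, 2)
  expect_setequal(st1[["2"]], igraph::V(s)$name)
})

test_that("layout is deterministic per seed and pulls connected pairs together", {
  g <- synth_graph(40, 2, seed = 1)
  expect_identical(layout_base(g, seed = 42), layout_base(g, seed = 42))
  p <- layout_base(g, seed = 42)
  expect_true(all(p >= 0 & p < 1))

  # connected pair vs disconnected pair over 20 seeds
  mk <- function(with_edge) {
    el <- rbind(c("a", "b"), c("a", "c"), c("b", "c"))
    if (with_edge) el <- rbind(el, c("x", "y"))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::add_vertices(g, sum(!c("x", "y") %in% igraph::V(g)$name),
                         name = setdiff(c("x", "y"), igraph::V(g)$name))
  }
  d_conn <- d_disc <- numeric(20)
  for (s in 1:20) {
    pc <- layout_base(mk(TRUE), seed = s)
    pd <- layout_base(mk(FALSE), seed = s)
    d_conn[s] <- sqrt(sum((pc["x", ] - pc["y", ])^2))
    d_disc[s] <- sqrt(sum((pd["x", ] - pd["y", ])^2))
  }
  expect_lt(mean(d_conn), mean(d_disc))
})

test_that("vertex splitting realizes every edge within d_max", {
  # no-op when the layout already satisfies d_max
  g <- igraph::graph_from_edgelist(rbind(c("a", "b")), directed = FALSE)
  pos <- rbind(a = c(0.4, 0.5), b = c(0.45, 0.5))
  sp <- split_vertices(g, pos, d_max = 0.15)
  expect_equal(nrow(sp$copies), 2)
  expect_equal(lengths(sp$registry), c(a = 1L, b = 1L))

  # opposite corners: exactly one extra copy, realization within d_max
  pos2 <- rbind(a = c(0.05, 0.05), b = c(0.95, 0.95))
  sp2 <- split_vertices(g, pos2, d_max = 0.15)
  expect_equal(nrow(sp2$copies), 3)
  expect_lte(sp2$realizations$dist, 0.15)

  # postcondition sweep on random graphs
  for (seed in 1:5) {
    gg <- synth_graph(60, 2, seed = seed)
    sp3 <- split_vertices(gg, layout_base(gg, seed = seed), d_max = 0.15)
    expect_equal(nrow(sp3$realizations), igraph::ecount(gg))
    expect_true(all(sp3$realizations$dist <= 0.15 + 1e-12))
    # registry covers every canonical node and every realized copy
    expect_setequal(names(sp3$registry), igraph::V(gg)$name)
    expect_true(all(c(sp3$realizations$from_copy,
                      sp3$realizations$to_copy) %in% sp3$copies$copy_id))
  }
  expect_error(split_vertices(g, pos2, d_max = 0), "d_max")
})

test_that("larger d_max never creates more copies", {
  gg <- synth_graph(50, 2, seed = 4)
  pos <- layout_base(gg, seed = 4)
  n_copies <- vapply(c(0.08, 0.15, 0.3, 0.6, 1.5), function(dm) {
    nrow(split_vertices(gg, pos, d_max = dm)$copies)
  }, numeric(1))
  expect_true(all(diff(n_copies) <= 0))
  expect_equal(n_copies[5], igraph::vcount(gg))  # huge d_max: no splits
})

test_that("the copy manifest lists every copy with its interactors", {
  gg <- synth_graph(30, 1, seed = 2)
  nb <- build_network(gg, 0, 2, seed = 2)
  man <- nb$manifests$copies
  expect_setequal(names(man), igraph::V(gg)$name)
  total <- sum(lengths(man))
  expect_equal(total, nrow(nb$split$copies))
  # every realized copy id appears in the registry
  reg_ids <- unlist(nb$split$registry, use.names = FALSE)
  expect_true(all(nb$split$realizations$from_copy %in% reg_ids))
  # an unsplit node has a single copy entry
  singles <- names(which(lengths(nb$split$registry) == 1))
  expect_gt(length(singles), 0)
  expect_length(man[[singles[1]]], 1)
})
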