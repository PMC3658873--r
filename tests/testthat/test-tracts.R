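# Curve distance, tract clustering, centroid selection, plane projection.

straight_tract <- function(id, from, to, n = 10) {
  tt <- seq(0, 1, length.out = n)
  list(id = id, points = outer(tt, to - from) + matrix(from, n, 3,
                                                       byrow = TRUE))
}

test_that("curve_distance is the symmetrized mean closest-point distance", {
  a <- straight_tract("a", c(0, 0, 0), c(10, 0, 0))
  expect_equal(curve_distance(a, a), 0)
  # parallel segment offset by d
  b <- straight_tract("b", c(0, 3, 0), c(10, 3, 0))
  expect_equal(curve_distance(a, b), 3)

  # brute-force double loop on hand-placed 3-point curves
  p <- list(id = "p", points = rbind(c(0, 0, 0), c(1, 2, 0), c(3, 1, 1)))
  q <- list(id = "q", points = rbind(c(0, 1, 1), c(2, 2, 2), c(4, 0, 0)))
  brute <- function(x, y) {
    mins <- apply(x$points, 1, function(pt) {
      min(apply(y$points, 1, function(qt) sqrt(sum((pt - qt)^2))))
    })
    mean(mins)
  }
  expect_equal(curve_distance(p, q), (brute(p, q) + brute(q, p)) / 2,
               tolerance = 1e-12)

  # symmetry and point-set identity on random tracts
  fx <- synth_tracts(2, 3, 8, spread = 1, seed = 5)
  for (i in 1:3) {
    x <- fx$tracts[[i]]; y <- fx$tracts[[i + 3]]
    expect_equal(curve_distance(x, y), curve_distance(y, x))
    rev_x <- list(id = "r", points = x$points[nrow(x$points):1, ])
    expect_equal(curve_distance(x, rev_x), 0, tolerance = 1e-6)  # same set
  }
})

test_that("clustering recovers planted bundles and picks optimal centroids", {
  fx <- synth_tracts(3, 12, 15, spread = 0.3, seed = 8)
  cl <- cluster_tracts(fx$tracts, 3)
  lab <- integer(0)
  for (i in seq_along(cl)) lab[cl[[i]]$members] <- i
  expect_equal(ari(lab[names(fx$labels)], fx$labels), 1)

  dmat <- curve_distance_matrix(fx$tracts)
  for (c in cl) {
    mem <- c$members
    sums <- rowSums(dmat[mem, mem, drop = FALSE])
    expect_equal(sums[[c$centroid_id]], min(sums))
    expect_true(c$centroid_id %in% mem)
    expect_equal(c$stats$n, length(mem))
    expect_equal(c$stats$mean_centroid_distance,
                 mean(dmat[c$centroid_id, mem]))
  }

  # k = n gives singletons, each its own centroid
  sing <- cluster_tracts(fx$tracts[1:4], 4)
  expect_true(all(vapply(sing, function(c) {
    c$stats$n == 1 && c$centroid_id == c$members
  }, logical(1))))
  expect_error(cluster_tracts(fx$tracts, 0), "k")
})

test_that("plane projections drop one axis each and jointly preserve 3D", {
  pts <- matrix(rnorm(30), 10, 3)
  for (pl in c("sagittal", "coronal", "transverse")) {
    proj <- drop_axis(pts, pl)
    expect_identical(drop_axis(proj, pl), proj)  # idempotent
    ax <- switch(pl, sagittal = 1, coronal = 2, transverse = 3)
    expect_true(all(proj[, ax] == 0))
    expect_identical(proj[, -ax], pts[, -ax])
  }
  # the three projections jointly recover every coordinate
  sag <- drop_axis(pts, "sagittal")      # keeps y, z
  cor_ <- drop_axis(pts, "coronal")      # keeps x, z
  tra <- drop_axis(pts, "transverse")    # keeps x, y
  rebuilt <- cbind(cor_[, 1], tra[, 2], sag[, 3])
  expect_equal(unname(rebuilt), unname(pts))
})

test_that("projected clusters link members from the centroid's endpoints", {
  fx <- synth_tracts(2, 7, 10, spread = 0.2, seed = 3)
  cl <- cluster_tracts(fx$tracts, 2)
  pr <- project_tracts(cl, fx$tracts, "transverse")
  for (i in seq_along(cl)) {
    expect_length(pr$links[[i]], 2 * cl[[i]]$stats$n)
    expect_true(all(pr$centroids[[i]] >= 0 & pr$centroids[[i]] <= 1))
  }
  # a single straight tract projects to a straight 2D segment
  tr <- straight_tract("t", c(0, 0, 0), c(10, 5, 2))
  one <- cluster_tracts(list(tr), 1)
  p1 <- project_tracts(one, list(tr), "transverse")$centroids[[1]]
  fit <- lm(p1[, 2] ~ p1[, 1])
  expect_lt(max(abs(residuals(fit))), 1e-12)
  # degenerate extent on a kept axis warns but still scales
  flat <- straight_tract("f", c(0, 0, 0), c(0, 0, 5))
  expect_warning(project_tracts(cluster_tracts(list(flat), 1), list(flat),
                                "transverse"), "degenerate")
})
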