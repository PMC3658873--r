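# Genome track layout, glyph spreading (with the exact 1D packing
# oracle), highlight icons.

test_that("anchors are affine in base-pair coordinates per chromosome", {
  fx <- synth_genome(n_genes = 60, n_chrom = 3, dense_fraction = 0.4,
                     seed = 1)
  ly <- layout_genome(fx$annotations, fx$chrom_lengths)
  g <- ly$genes
  for (cc in unique(g$chrom)) {
    i <- which(g$chrom == cc)
    mid <- (fx$annotations$start + fx$annotations$end)[
      match(g$gene_id[i], fx$annotations$gene_id)] / 2
    fit <- lm(g$anchor_x[i] ~ mid)
    expect_lt(max(abs(residuals(fit))), 1e-12)
    # genomic order equals display order along x
    expect_false(is.unsorted(g$anchor_x[i]))
  }
  # shared scale: a chromosome half as long occupies half the width
  expect_equal(ly$chroms$band_width,
               as.numeric(fx$chrom_lengths) / max(fx$chrom_lengths))
  # single gene at a chromosome midpoint anchors at the band middle
  ann1 <- data.frame(chrom = "1", start = 450, end = 550, strand = "+",
                     gene_id = "g")
  ly1 <- layout_genome(ann1, c("1" = 1000))
  expect_equal(ly1$genes$anchor_x, 0.5)
  expect_error(layout_genome(ann1[0, ]), "no annotations")
})

test_that("chromosome names sort naturally", {
  expect_equal(natural_chrom_order(c("10", "2", "X", "1", "MT", "Y")),
               c("1", "2", "10", "X", "Y", "MT"))
  expect_equal(natural_chrom_order(c("chr2", "chr11", "chr1")),
               c("chr1", "chr2", "chr11"))
})

test_that("spreading is a no-op on sparse layouts", {
  ann <- data.frame(chrom = "1", start = c(0, 4e6, 8e6),
                    end = c(1e6, 5e6, 9e6), strand = "+",
                    gene_id = c("a", "b", "c"))
  ly <- spread_glyphs(layout_genome(ann, c("1" = 1e7)), min_width = 8,
                      pyramid = tile_pyramid(2))
  g <- ly$genes
  expect_equal(g$disp_x0, g$x0)
  expect_equal(g$disp_x1, g$x1)
  expect_equal(g$leader_from_x, g$leader_to_x)  # zero-length leaders
})

test_that("two co-located genes are pushed apart symmetrically", {
  ann <- data.frame(chrom = "1", start = c(5e6, 5e6), end = c(5e6 + 10, 5e6 + 10),
                    strand = "+", gene_id = c("a", "b"))
  p <- tile_pyramid(2)
  w_min <- 8 / (256 * 4)
  ly <- spread_glyphs(layout_genome(ann, c("1" = 1e7)), min_width = 8,
                      pyramid = p)
  g <- ly$genes
  disp <- (g$disp_x0 + g$disp_x1) / 2 - g$anchor_x
  expect_equal(disp, c(-w_min / 2, w_min / 2))
})

test_that("dense layouts match the exact isotonic packing oracle", {
  p <- tile_pyramid(3)
  w_min <- 8 / (256 * 8)
  for (seed in 1:5) {
    # 50 glyphs crammed into 5% of the band
    starts <- with_test_seed(seed, sort(round(runif(50, 0.40, 0.45) * 1e7)))
    ann <- data.frame(chrom = "1", start = starts, end = starts + 10,
                      strand = "+", gene_id = sprintf("g%02d", 1:50))
    ly <- spread_glyphs(layout_genome(ann, c("1" = 1e7)), min_width = 8,
                        pyramid = p)
    g <- ly$genes
    centers <- (g$disp_x0 + g$disp_x1) / 2
    # zero overlap at z_max, order preserved
    expect_true(all(diff(centers) >= w_min - 1e-12))
    expect_false(is.unsorted(centers))
    # independent oracle: isotonic regression on spacing-shifted anchors
    cum <- (seq_len(50) - 1) * w_min
    oracle <- stats::isoreg(g$anchor_x - cum)$yf + cum
    expect_equal(centers, oracle, tolerance = 1e-10)
  }
})

test_that("an overfull chromosome names itself and the z_max that fits", {
  starts <- seq(0, 990, by = 10)
  ann <- data.frame(chrom = "7", start = starts, end = starts + 5,
                    strand = "+", gene_id = sprintf("g%03d", seq_along(starts)))
  expect_error(
    spread_glyphs(layout_genome(ann, c("7" = 1000)), min_width = 8,
                  pyramid = tile_pyramid(0)),
    "chromosome 7.*z_max")
})

test_that("highlight icons peak at the center, vanish at the rim, and amplify", {
  ic <- make_highlight_icon(10, peak_opacity = 0.5)
  ctr <- c(11, 11)
  expect_equal(ic[ctr[1], ctr[2]], 0.5)
  expect_equal(ic[1, 1], 0)           # corner is beyond the radius
  expect_equal(ic[11, 21], 0)         # exactly at the radius
  # opacity non-increasing with distance along a ray
  expect_true(all(diff(ic[11, 11:21]) <= 0))
  expect_error(make_highlight_icon(0), "radius")
  expect_error(make_highlight_icon(5, 1.5), "peak_opacity")

  # two co-located markers: 1 - (1 - 0.5)^2 = 0.75 at the center
  two <- composite_icons(list(ic, ic))
  expect_equal(two[11, 11], 0.75)
  # monotone amplification in marker count, saturating below 1
  prev <- 0
  for (k in 1:6) {
    v <- composite_icons(rep(list(ic), k))[11, 11]
    expect_gt(v, prev)
    expect_lt(v, 1)
    prev <- v
  }
})

test_that("glyph identity is preserved at every zoom (no aggregation)", {
  fx <- synth_genome(n_genes = 30, n_chrom = 2, dense_fraction = 0.5,
                     seed = 3)
  gb <- build_genome(fx$annotations, pyramid = tile_pyramid(2))
  for (z in 0:2) {
    prims <- genomaps:::scene_prims(gb$scene, z)
    types <- vapply(prims, `[[`, character(1), "type")
    expect_equal(sum(types == "rect"), 30)  # one glyph per gene, every zoom
  }
})
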