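# Random selectable-element fixtures and the brute-force hit oracle,
# shared by the hit-grid unit tests and the end-to-end checks.

random_elements <- function(n, seed) {
  with_test_seed(seed, {
    lapply(seq_len(n), function(i) {
      id <- sprintf("el%04d", i)
      kind <- sample(c("point", "polyline", "rect"), 1)
      if (kind == "point") {
        selectable_element(id, "point", runif(2, 0, 0.999))
      } else if (kind == "rect") {
        p <- runif(2, 0, 0.9)
        selectable_element(id, "rect", c(p, p + runif(2, 0.005, 0.08)))
      } else {
        k <- sample(3:6, 1)
        start <- runif(2, 0.1, 0.9)
        steps <- matrix(runif(2 * (k - 1), -0.05, 0.05), k - 1, 2)
        v <- rbind(start, start + apply(steps, 2, cumsum))
        v <- pmin(pmax(v, 0), 0.999)
        selectable_element(id, "polyline", v)
      }
    })
  })
}

brute_hit <- function(px, py, elements, tolerance) {
  d <- vapply(elements, function(e) element_distance(px, py, e), numeric(1))
  ids <- vapply(elements, `[[`, character(1), "id")
  o <- order(d, ids)
  if (d[o[1]] <= tolerance) ids[o[1]] else NULL
}
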