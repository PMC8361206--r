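# Build a small prediction set with known layer values.
toy_preds <- function(probs, thresholds = NULL, ciw = NULL, n = 4) {
  species <- names(probs)
  mk <- function(v) raster_grid(matrix(v, n, n))
  if (is.null(thresholds)) thresholds <- setNames(rep(0.5, length(probs)), species)
  prob_layers <- lapply(probs, mk)
  bin_layers <- lapply(species, function(s)
    binarize(prob_layers[[s]], thresholds[[s]]))
  ciw_layers <- if (is.null(ciw)) lapply(probs, function(p) mk(p * 0.1))
                else lapply(ciw, mk)
  species_prediction_set(species, prob_layers, bin_layers, thresholds,
                         ciw_layers)
}

test_that("extraction at units follows the cell-centre and floor conventions", {
  set.seed(71)
  probs <- list(A = runif(16), B = runif(16))
  preds <- toy_preds(probs)
  units <- data.frame(unit_id = c("u1", "u2", "u3"),
                      x = c(0.5, 0.7, 2.0), y = c(3.5, 3.2, 2.0))
  ex <- extract_at_units(preds, units)
  # u1 at the centre of cell (1,1)
  expect_equal(ex$probability["u1", "A"], preds$mean_probability$A$values[1, 1])
  # u1 and u2 share cell (1,1)
  expect_equal(ex$probability["u1", ], ex$probability["u2", ])
  # boundary point (2,2): floor rule -> col 3, row 3
  expect_equal(ex$probability["u3", "B"], preds$mean_probability$B$values[3, 3])
  expect_error(extract_at_units(preds, data.frame(unit_id = "bad", x = 9, y = 1)),
               "outside")
})

test_that("binary and probability stacks match loop oracles", {
  set.seed(72)
  probs <- list(A = runif(16), B = runif(16), C = runif(16))
  preds <- toy_preds(probs)
  bs <- stack_binary(preds)
  ps <- stack_probability(preds)
  for (cell in 1:16) {
    bsum <- 0; psum <- 0
    for (s in names(probs)) {
      bsum <- bsum + (probs[[s]][cell] >= 0.5)
      psum <- psum + probs[[s]][cell]
    }
    expect_equal(unname(bs$richness[cell]), bsum)
    expect_equal(unname(ps$richness[cell]), psum)
  }
  expect_equal(unname(bs$richness), unname(rowSums(bs$composition)))

  zero <- toy_preds(list(A = rep(0, 16), B = rep(0, 16)))
  expect_true(all(stack_binary(zero)$richness == 0))
  expect_true(all(stack_probability(zero)$richness == 0))

  bad <- toy_preds(probs)
  bad$mean_probability$A$values[1, 1] <- 1.2
  expect_error(stack_probability(bad), "outside")
})

test_that("PRR stacking equals the sort-and-take-k oracle, ties included", {
  probs <- list(A = rep(0.9, 16), B = rep(0.7, 16), C = rep(0.4, 16))
  preds <- toy_preds(probs)
  cs <- stack_constrained_prr(preds, 2)
  expect_true(all(cs$composition[, c("A", "B")] == 1))
  expect_true(all(cs$composition[, "C"] == 0))
  expect_true(all(stack_constrained_prr(preds, 5)$composition == 1))
  expect_error(stack_constrained_prr(preds, -1), ">= 0")

  set.seed(73)
  for (rep_i in 1:20) {
    sp <- paste0("s", 1:6)
    pr <- setNames(lapply(sp, function(s)
      sample(c(0.2, 0.5, 0.8), 16, replace = TRUE)), sp)  # forces ties
    pd <- toy_preds(pr)
    k <- sample(0:6, 16, replace = TRUE)
    got <- stack_constrained_prr(pd, k)
    for (cell in 1:16) {
      pvec <- sapply(pr, `[`, cell)
      # oracle: stable sort by descending probability, alphabetical on ties
      ord <- order(-pvec, names(pvec))
      want_set <- names(pvec)[ord][seq_len(min(k[cell], 6))]
      got_set <- colnames(got$composition)[got$composition[cell, ] == 1]
      expect_setequal(got_set, want_set)
      expect_equal(unname(got$richness[cell]), min(k[cell], 6))
    }
  }
})

test_that("site aggregation unions composition and maxes probabilities", {
  pm <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3,
               dimnames = list(c("p1", "p2"), c("A", "B", "C")))
  h <- data.frame(plot_id = c("p1", "p2"), site_id = "s1")
  agg <- aggregate_to_sites(new_assemblage_for_test(pm, "binary"), h)
  expect_equal(unname(agg$composition["s1", ]), c(1, 1, 0))

  # single-plot site is the identity
  h2 <- data.frame(plot_id = c("p1", "p2"), site_id = c("s1", "s2"))
  agg2 <- aggregate_to_sites(new_assemblage_for_test(pm, "binary"), h2)
  expect_equal(unname(agg2$composition["s1", ]), unname(pm["p1", ]))

  probm <- matrix(c(0.2, 0.6, 0.3, 0.1), 2, 2,
                  dimnames = list(c("p1", "p2"), c("A", "B")))
  aggp <- aggregate_to_sites(new_assemblage_for_test(probm, "probability"), h)
  expect_equal(unname(aggp$composition["s1", "A"]), 0.6)
  aggi <- aggregate_to_sites(new_assemblage_for_test(probm, "probability"), h,
                             prob_rule = "one_minus_prod")
  expect_equal(unname(aggi$composition["s1", "A"]), 1 - 0.8 * 0.4)

  # idempotent and order-independent
  again <- aggregate_to_sites(agg, data.frame(plot_id = "s1", site_id = "s1"))
  expect_equal(again$composition, agg$composition)
  rev_pm <- pm[2:1, ]
  agg_rev <- aggregate_to_sites(new_assemblage_for_test(rev_pm, "binary"), h)
  expect_equal(agg_rev$composition, agg$composition)

  h_orphan <- data.frame(plot_id = "p1", site_id = "s1")
  expect_error(aggregate_to_sites(new_assemblage_for_test(pm, "binary"), h_orphan),
               "orphan")
})

test_that("stacked uncertainty is the per-cell sum of CI widths", {
  set.seed(74)
  ciw <- list(A = runif(16), B = runif(16), C = runif(16))
  preds <- toy_preds(list(A = runif(16), B = runif(16), C = runif(16)),
                     ciw = ciw)
  u <- stack_uncertainty(preds)
  for (cell in 1:16)
    expect_equal(as.vector(u$values)[cell],
                 ciw$A[cell] + ciw$B[cell] + ciw$C[cell])
  one <- toy_preds(list(A = runif(16)), ciw = list(A = ciw$A))
  expect_equal(as.vector(stack_uncertainty(one)$values), ciw$A)
  zero <- toy_preds(list(A = runif(16)), ciw = list(A = rep(0, 16)))
  expect_true(all(stack_uncertainty(zero)$values == 0))
})

test_that("PRR richness never exceeds its constraint nor the bS count when capped", {
  set.seed(75)
  probs <- setNames(lapply(1:5, function(i) runif(16)), paste0("s", 1:5))
  preds <- toy_preds(probs)
  k <- sample(0:5, 16, replace = TRUE)
  cs <- stack_constrained_prr(preds, k)
  expect_true(all(cs$richness <= k))
  bs <- stack_binary(preds)
  capped <- which(k <= bs$richness)
  expect_true(all(cs$richness[capped] <= bs$richness[capped]))
})
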