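# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and straight-from-definition
# arithmetic.

# Lag-1 Moran's I with rook (4-neighbour) weights.
morans_i_rook <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; wsum <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) { num <- num + 2 * z[i, j] * z[i + 1, j]; wsum <- wsum + 2 }
    if (j < nc) { num <- num + 2 * z[i, j] * z[i, j + 1]; wsum <- wsum + 2 }
  }
  (length(m) / wsum) * num / sum(z^2)
}

# Straight-from-formula bioclim for one cell's 12-month series.
bioclim_scalar <- function(tmin, tmax, prec, plus_one = TRUE) {
  tavg <- (tmin + tmax) / 2
  q <- function(m) ((m - 1):(m + 1)) %% 12 + 1
  qt <- sapply(1:12, function(m) mean(tavg[q(m)]))
  qp <- sapply(1:12, function(m) sum(prec[q(m)]))
  out <- numeric(19)
  out[1] <- mean(tavg)
  out[2] <- mean(tmax - tmin)
  out[5] <- max(tmax); out[6] <- min(tmin); out[7] <- out[5] - out[6]
  out[3] <- if (out[7] > 0) 100 * out[2] / out[7] else 0
  out[4] <- 100 * sd(tavg)
  out[8] <- qt[which.max(qp)]; out[9] <- qt[which.min(qp)]
  out[10] <- qt[which.max(qt)]; out[11] <- qt[which.min(qt)]
  out[12] <- sum(prec)
  out[13] <- max(prec); out[14] <- min(prec)
  den <- if (plus_one) 1 + mean(prec) else mean(prec)
  out[15] <- if (den != 0) 100 * sd(prec) / den else 0
  out[16] <- qp[which.max(qp)]; out[17] <- qp[which.min(qp)]
  out[18] <- qp[which.max(qt)]; out[19] <- qp[which.min(qt)]
  out
}

# AUC by enumeration of all positive-negative pairs (ties half credit).
auc_brute <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

tss_brute <- function(p, y, th) {
  pred <- p >= th
  sum(pred & y == 1) / sum(y == 1) + sum(!pred & y == 0) / sum(y == 0) - 1
}

# Dense-grid threshold scan (independent of the candidate-set scan).
best_tss_grid <- function(p, y, grid = seq(0, 1, length.out = 1001)) {
  vals <- sapply(grid, function(t) tss_brute(p, y, t))
  max(vals)
}

# Exhaustive maximum independent set size for thinning instances.
max_retained_brute <- function(x, y, distance) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  best <- 0
  for (code in 0:(2^n - 1)) {
    keep <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(keep) <= best) next
    ok <- TRUE
    if (length(keep) > 1) {
      dd <- d[keep, keep]
      ok <- all(dd[upper.tri(dd)] >= distance)
    }
    if (ok) best <- length(keep)
  }
  best
}

# Small random landscape shared by several tests.
tiny_landscape <- function(seed = 42, n = 16, n_covariates = 2) {
  generate_landscape(landscape_config(n_rows = n, n_cols = n, cell_size = 1,
                                      autocorr_range = 4,
                                      n_covariates = n_covariates,
                                      seed = seed))
}

rand_grid <- function(n = 4, seed = NULL, f = stats::runif) {
  if (!is.null(seed)) set.seed(seed)
  raster_grid(matrix(f(n * n), n, n))
}

# Mantel statistic: Pearson correlation of lower-triangle distances.
mantel_r <- function(d1, d2) {
  cor(d1[lower.tri(d1)], d2[lower.tri(d2)])
}

# Prevalence recovery under the reference fixture conditions: fits one
# reduced-size BART per virtual species and correlates landscape-mean
# predicted probability with true prevalence. Memoised: two test files use
# the same quantity.
prevalence_recovery <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    land <- generate_landscape(landscape_config(
      n_rows = 24, n_cols = 24, autocorr_range = 6, n_covariates = 3,
      microhabitat = TRUE, seed = 21))
    spt <- generate_species_and_tree(12, 0.5, land, seed = 22)
    occ <- realize_occurrences(spt$niches, land, 150, 0.5, seed = 23)
    stack <- setNames(land$covariates,
                      sapply(land$covariates, function(g) g$name))
    g0 <- land$covariates[[1]]
    true_prev <- sapply(occ$true_state$probability,
                        function(g) mean(g$values))
    pred_prev <- sapply(seq_along(spt$niches), function(i) {
      sp <- spt$niches[[i]]$species_id
      tab <- occ$occurrences[occ$occurrences$species_id == sp, ]
      thin <- thin_occurrences(tab, thinning_distance_rule(nrow(tab)), 10,
                               seed = 30 + i)
      pa <- sample_pseudoabsences(accessible_area(thin, 300, land),
                                  nrow(thin),
                                  cell_index(g0, thin$x, thin$y)$cell, g0,
                                  seed = 60 + i, species_id = sp)
      pts <- rbind(thin[, c("x", "y")], pa[, c("x", "y")])
      X <- sapply(stack, function(g) extract_values(g, pts$x, pts$y))
      fit <- fit_bart(X, c(rep(1, nrow(thin)), rep(0, nrow(pa))),
                      bart_test_config(seed = 90 + i))
      mean(predict(fit, stack, thin_draws = 60)$mean_probability$values)
    })
    cache <<- list(true = true_prev, predicted = pred_prev)
    cache
  }
})

# Assemblage container built by hand (independent of package constructors).
new_assemblage_for_test <- function(m, type) {
  structure(list(unit_ids = rownames(m), composition = m,
                 richness = rowSums(m), type = type),
            class = "assemblage_prediction")
}
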