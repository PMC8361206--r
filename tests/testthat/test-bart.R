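# Shared small fixture: separable step-function labels on covariate 1.
step_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  list(X = X, y = as.numeric(X[, 1] > 0.3))
}

test_that("probit BART separates a step function and is deterministic", {
  d <- step_data()
  fit <- fit_bart(d$X, d$y, bart_test_config(seed = 7))
  expect_s3_class(fit, "bart_sdm")
  diag <- evaluate_model(fitted(fit), d$y)
  expect_gte(diag$auc, 0.95)
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  fit2 <- fit_bart(d$X, d$y, bart_test_config(seed = 7))
  expect_identical(fitted(fit), fitted(fit2))
  expect_false(identical(fitted(fit),
                         fitted(fit_bart(d$X, d$y, bart_test_config(seed = 8)))))
})

test_that("degenerate designs are rejected", {
  d <- step_data(60)
  expect_error(fit_bart(d$X, rep(1, 60), bart_test_config()), "both classes")
  Xc <- matrix(1, 60, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_bart(Xc, d$y, bart_test_config()), "zero-variance")
  expect_error(fit_bart(d$X[1:10, ], d$y, bart_test_config()), "sizes differ")
})

test_that("posterior predictions are consistent, spread out, and wider off-support", {
  d <- step_data(200, seed = 2)
  fit <- fit_bart(d$X, d$y, bart_test_config(seed = 3))
  pr <- predict(fit, d$X)
  expect_equal(pr$mean_probability, fitted(fit), tolerance = 1e-12)
  expect_true(all(pr$ci_width > 0))

  # far outside the training covariate range the posterior is at least as
  # uncertain as a typical in-range point
  far <- cbind(x1 = runif(50, 8, 12), x2 = runif(50, 8, 12))
  pr_far <- predict(fit, far)
  expect_gte(median(pr_far$ci_width), median(pr$ci_width))

  expect_error(predict(fit, matrix(0, 3, 1, dimnames = list(NULL, "zz"))),
               "missing covariates")
})

test_that("raster-stack prediction matches pointwise prediction", {
  land <- tiny_landscape(n_covariates = 2)
  stack <- setNames(land$covariates, c("x1", "x2"))
  d <- step_data(150, seed = 4)
  fit <- fit_bart(d$X, d$y, bart_test_config(seed = 5, n_trees = 10,
                                             n_iterations = 100))
  pred <- predict(fit, stack)
  expect_s3_class(pred$mean_probability, "raster_grid")
  cc <- cell_centers(stack$x1)
  Xg <- cbind(x1 = extract_values(stack$x1, cc$x, cc$y),
              x2 = extract_values(stack$x2, cc$x, cc$y))
  pp <- predict(fit, Xg)
  expect_equal(as.vector(pred$mean_probability$values)[cc$row + (cc$col - 1) * 16],
               pp$mean_probability, tolerance = 1e-12)
  expect_error(predict(fit, stack[1]), "missing")
})

test_that("posterior mean is monotone across a 1-D step within MC tolerance", {
  set.seed(6)
  n <- 400
  X <- cbind(x1 = sort(runif(n, -2, 2)))
  y <- rbinom(n, 1, ifelse(X[, 1] > 0, 0.9, 0.1))
  fit <- fit_bart(X, y, bart_test_config(seed = 11))
  grid <- cbind(x1 = seq(-1.8, 1.8, length.out = 25))
  p <- predict(fit, grid)$mean_probability
  # monotone within Monte-Carlo tolerance: no drop larger than 0.1
  expect_true(all(diff(p) > -0.1))
  expect_lt(mean(p[1:10]), 0.2)
  expect_gt(mean(p[16:25]), 0.8)
})

test_that("variable importance sums to 100 and finds the signal covariate", {
  d <- step_data(200, seed = 12)
  fit <- fit_bart(d$X, d$y, bart_test_config(seed = 13))
  imp <- variable_importance(fit)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_true(all(imp >= 0))

  one <- fit_bart(d$X[, 1, drop = FALSE], d$y,
                  bart_test_config(seed = 14, n_trees = 5, n_iterations = 50))
  expect_equal(unname(variable_importance(one)), 100)

  # signal vs pure noise, median over 5 seeds
  diffs <- sapply(1:5, function(s) {
    set.seed(100 + s)
    X <- cbind(signal = runif(150, -2, 2), noise = runif(150, -2, 2))
    y <- as.numeric(X[, 1] > 0)
    f <- fit_bart(X, y, bart_test_config(seed = s, n_trees = 10,
                                         n_iterations = 120))
    imp <- variable_importance(f)
    imp["signal"] - imp["noise"]
  })
  expect_gt(median(diffs), 0)
})

test_that("AUC and TSS match enumeration oracles, including the worked cases", {
  expect_equal(evaluate_model(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(evaluate_model(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  const <- evaluate_model(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(const$auc, 0.5)
  expect_equal(const$tss, 0)
  expect_error(evaluate_model(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(41)
  for (rep_i in 1:40) {
    n <- sample(5:50, 1)
    p <- round(runif(n), sample(c(1, 2, 7), 1))  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(evaluate_model(p, y)$auc, auc_brute(p, y), tolerance = 1e-12)
  }
})

test_that("TSS threshold search equals dense-grid and exhaustive scans", {
  expect_equal(tss_threshold(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 0.8)
  ev <- evaluate_model(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$tss, 1)

  set.seed(42)
  for (rep_i in 1:30) {
    n <- sample(6:40, 1)
    p <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    th <- tss_threshold(p, y)
    expect_equal(tss_brute(p, y, th), best_tss_grid(p, y), tolerance = 1e-12)
    # smallest attaining candidate
    cand <- sort(unique(p))
    attaining <- cand[sapply(cand, function(t)
      abs(tss_brute(p, y, t) - tss_brute(p, y, th)) < 1e-12)]
    expect_equal(th, min(attaining))
  }
})

test_that("binarization respects thresholds and is monotone", {
  p <- c(0, 0.2, 0.5, 0.8, 1)
  expect_equal(binarize(p, 0), rep(1, 5))
  expect_equal(binarize(p, 1), c(0, 0, 0, 0, 1))
  probs <- runif(30)
  counts <- sapply(seq(0, 1, 0.1), function(t) sum(binarize(probs, t)))
  expect_true(all(diff(counts) <= 0))
  g <- raster_grid(matrix(c(0.1, 0.6, 0.4, 0.9), 2, 2))
  expect_equal(binarize(g, 0.5)$values, matrix(c(0, 1, 0, 1), 2, 2))
})

test_that("backward covariate elimination keeps the signal covariate", {
  set.seed(51)
  n <- 150
  X <- cbind(sig = runif(n, -2, 2), n1 = runif(n), n2 = runif(n))
  y <- as.numeric(X[, 1] > 0)
  cfg <- bart_test_config(seed = 1, n_trees = 10, n_iterations = 100)
  sel <- select_covariates(X, y, cfg, tolerance = 0.05, n_folds = 3, seed = 2)
  expect_lte(length(sel$retained), 3)
  expect_true("sig" %in% sel$retained)
  expect_true(all(diff(sel$trace$n_covariates) == -1))

  sel1 <- select_covariates(X, y, cfg, tolerance = Inf, n_folds = 3, seed = 2)
  expect_length(sel1$retained, 1)
  expect_error(select_covariates(X[, 1, drop = FALSE], y, cfg), "at least 2")
})

test_that("prevalence recovery: predicted mean prevalence ranks true prevalence", {
  rec <- prevalence_recovery()
  expect_gt(cor(rec$true, rec$predicted, method = "spearman"), 0.8)
})
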