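#' Evaluate a probabilistic occurrence model
#'
#' AUC is the Mann-Whitney rank statistic (probability that a random
#' presence outranks a random absence, ties counted half). TSS (sensitivity
#' + specificity - 1) is reported at the TSS-maximizing threshold found by
#' [tss_threshold()].
#'
#' @param probabilities predicted probabilities per point.
#' @param labels 0/1 observed labels.
#' @return list with `auc`, `tss`, `threshold`.
#' @export
evaluate_model <- function(probabilities, labels) {
  check_two_classes(labels, probabilities)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  rk <- rank(probabilities)
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- tss_threshold(probabilities, labels)
  list(auc = auc, tss = tss_at(probabilities, labels, th), threshold = th)
}

check_two_classes <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present to evaluate the model")
  invisible(TRUE)
}

tss_at <- function(probabilities, labels, threshold) {
  pred <- probabilities >= threshold
  sens <- sum(pred & labels == 1) / sum(labels == 1)
  spec <- sum(!pred & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' TSS-maximizing binarization threshold
#'
#' Scans every candidate threshold (the sorted unique predicted values) with
#' the binarization rule `probability >= threshold` and returns the smallest
#' candidate attaining the maximum TSS.
#'
#' @inheritParams evaluate_model
#' @return threshold in \[0, 1\].
#' @export
tss_threshold <- function(probabilities, labels) {
  check_two_classes(labels, probabilities)
  cand <- sort(unique(probabilities))
  tss <- vapply(cand, function(t) tss_at(probabilities, labels, t), numeric(1))
  cand[which.max(tss > max(tss) - 1e-12)]
}

#' Binarize a probability prediction
#'
#' Marks cells (or points) present where the posterior mean probability is at
#' least the threshold.
#'
#' @param prediction a [predict.bart_sdm()] result, a [raster_grid()], or a
#'   numeric vector of probabilities.
#' @param threshold value in \[0, 1\].
#' @return same shape as the input probabilities, valued 0/1.
#' @export
binarize <- function(prediction, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  p <- if (is.list(prediction) && !inherits(prediction, "raster_grid"))
    prediction$mean_probability else prediction
  if (inherits(p, "raster_grid")) {
    raster_grid((p$values >= threshold) * 1, p$xmin, p$ymin, p$cell_size,
                paste0("binary_", p$name))
  } else (p >= threshold) * 1
}

#' Covariate importance of a fitted BART model
#'
#' The share of splitting rules that use each covariate, pooled over all
#' retained posterior draws, scaled to percentages.
#'
#' @param model a [fit_bart()] model.
#' @return named numeric vector summing to 100. Covariates never used split
#'   0 percent.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "bart_sdm"))
  tot <- colSums(model$split_counts)
  if (sum(tot) == 0) tot <- rep(1, length(tot))  # stumps only: uniform
  stats::setNames(100 * tot / sum(tot), model$covariate_names)
}

#' Backward covariate elimination for BART occurrence models
#'
#' Iteratively drops the covariate with the lowest importance, accepting the
#' drop while the stratified cross-validated AUC does not fall by more than
#' `tolerance`. Returns the retained covariate names and the nested-model
#' trace.
#'
#' @param x covariate matrix (named columns), >= 2 covariates.
#' @param y 0/1 labels.
#' @param config a [bart_config()] used for every fit.
#' @param tolerance maximum acceptable drop in mean cross-validated AUC
#'   (default 0.01; `Inf` eliminates down to a single covariate).
#' @param n_folds stratified cross-validation folds.
#' @param seed integer seed (fold assignment and fit seeds).
#' @return list with `retained` (character), `trace` (data.frame of step,
#'   n_covariates, cv_auc, dropped).
#' @export
select_covariates <- function(x, y, config = bart_test_config(),
                              tolerance = 0.01, n_folds = 4, seed = 1) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need at least 2 covariates to select among")
  folds <- with_seed(seed, make_folds(y, n_folds))
  cv_auc <- function(vars) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- fit_bart(X[tr, vars, drop = FALSE], y[tr],
                      utils::modifyList(config, list(seed = config$seed + f)))
      p <- predict(fit, X[!tr, vars, drop = FALSE])$mean_probability
      pos <- y[!tr] == 1
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      rk <- rank(p)
      (sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  cur <- colnames(X)
  auc_cur <- cv_auc(cur)
  trace <- data.frame(step = 0L, n_covariates = length(cur), cv_auc = auc_cur,
                      dropped = NA_character_, stringsAsFactors = FALSE)
  step <- 0L
  while (length(cur) > 1) {
    fit <- fit_bart(X[, cur, drop = FALSE], y, config)
    imp <- variable_importance(fit)
    worst <- names(which.min(imp))
    cand <- setdiff(cur, worst)
    auc_cand <- cv_auc(cand)
    if (!is.infinite(tolerance) && auc_cur - auc_cand > tolerance) break
    step <- step + 1L
    cur <- cand; auc_cur <- auc_cand
    trace <- rbind(trace, data.frame(step = step, n_covariates = length(cur),
                                     cv_auc = auc_cur, dropped = worst,
                                     stringsAsFactors = FALSE))
  }
  list(retained = cur, trace = trace)
}

make_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}
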