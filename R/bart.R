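#' BART sampler configuration
#'
#' Settings for the probit Bayesian additive regression tree sampler. The
#' defaults follow the standard BART prior: `n_trees = 200` trees,
#' `n_iterations = 1000` backfitting MCMC iterations with 20% discarded as
#' burn-in, tree-depth prior `alpha * (1 + depth)^(-beta)` with
#' `alpha = 0.95`, `beta = 2`, and leaf-prior scale `k = 2` (leaf values are
#' N(0, sigma_mu^2) with `sigma_mu = 3 / (k * sqrt(n_trees))`, shrinking the
#' latent probit mean into roughly \[-3, 3\]). `bart_test_config()` is a
#' reduced configuration (20 trees, 200 iterations) for fast exercises.
#'
#' @param n_trees number of trees (>= 1).
#' @param n_iterations MCMC iterations.
#' @param burn_in_fraction fraction of iterations discarded, in \[0, 1).
#' @param alpha,beta tree-depth prior parameters.
#' @param k leaf-prior scale.
#' @param n_cutpoints maximum split candidates per covariate.
#' @param node_min minimum observations per leaf.
#' @param proposal_probs probabilities of the grow/prune/change proposals
#'   (the swap proposal is omitted).
#' @param seed integer seed.
#' @return a `bart_config` list.
#' @export
bart_config <- function(n_trees = 200, n_iterations = 1000,
                        burn_in_fraction = 0.2, alpha = 0.95, beta = 2,
                        k = 2, n_cutpoints = 100, node_min = 5,
                        proposal_probs = c(grow = 0.4, prune = 0.4, change = 0.2),
                        seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  if (alpha <= 0 || alpha >= 1 || beta < 0) stop("invalid tree prior parameters")
  structure(list(n_trees = as.integer(n_trees),
                 n_iterations = as.integer(n_iterations),
                 burn_in_fraction = burn_in_fraction, alpha = alpha,
                 beta = beta, k = k, n_cutpoints = as.integer(n_cutpoints),
                 node_min = as.integer(node_min),
                 proposal_probs = proposal_probs / sum(proposal_probs),
                 seed = as.integer(seed)),
            class = "bart_config")
}

#' @rdname bart_config
#' @param ... overrides passed to [bart_config()].
#' @export
bart_test_config <- function(...) {
  args <- utils::modifyList(list(n_trees = 20, n_iterations = 200), list(...))
  do.call(bart_config, args)
}

# Marginal log-likelihood contribution of a leaf holding residual sum s over
# n observations, up to terms that cancel in MH ratios (noise sd fixed at 1).
leaf_logmarg <- function(n, s, tau2) {
  0.5 * log(1 / (1 + n * tau2)) + tau2 * s^2 / (2 * (1 + n * tau2))
}

new_tree <- function(n_obs) {
  list(var = NA_integer_, cut = NA_real_, left = NA_integer_,
       right = NA_integer_, parent = NA_integer_, depth = 0L,
       mu = 0, alive = TRUE, node_of = rep(1L, n_obs), free = integer(0))
}

tree_counts <- function(tr) {
  leaves <- which(tr$alive & is.na(tr$var))
  internal <- which(tr$alive & !is.na(tr$var))
  nog <- internal[vapply(internal, function(nd)
    is.na(tr$var[tr$left[nd]]) && is.na(tr$var[tr$right[nd]]), logical(1))]
  list(leaves = leaves, nog = nog)
}

alloc_node <- function(tr) {
  if (length(tr$free) > 0) {
    id <- tr$free[1]; tr$free <- tr$free[-1]
  } else {
    id <- length(tr$var) + 1L
    tr$var[id] <- NA_integer_; tr$cut[id] <- NA_real_
    tr$left[id] <- NA_integer_; tr$right[id] <- NA_integer_
    tr$parent[id] <- NA_integer_; tr$depth[id] <- 0L
    tr$mu[id] <- 0; tr$alive[id] <- FALSE
  }
  list(tree = tr, id = id)
}

# One Metropolis-Hastings structure move on a single tree given partial
# residuals r. Returns the (possibly updated) tree.
update_tree_structure <- function(tr, X, r, cutpoints, usable, cfg, tau2) {
  cnt <- tree_counts(tr)
  single <- length(cnt$leaves) == 1
  pp <- cfg$proposal_probs
  move <- if (single) "grow" else
    sample(c("grow", "prune", "change"), 1, prob = pp)
  p_grow_here <- if (single) 1 else pp[["grow"]]
  psplit <- function(d) cfg$alpha * (1 + d)^(-cfg$beta)

  if (move == "grow") {
    leaf <- if (length(cnt$leaves) == 1) cnt$leaves else sample(cnt$leaves, 1)
    v <- if (length(usable) == 1) usable else sample(usable, 1)
    cuts <- cutpoints[[v]]
    cut <- cuts[sample.int(length(cuts), 1)]
    members <- which(tr$node_of == leaf)
    goleft <- X[members, v] <= cut
    nl <- sum(goleft); nr <- length(members) - nl
    if (nl < cfg$node_min || nr < cfg$node_min) return(tr)
    sl <- sum(r[members[goleft]]); sr <- sum(r[members[!goleft]])
    d <- tr$depth[leaf]
    dll <- leaf_logmarg(nl, sl, tau2) + leaf_logmarg(nr, sr, tau2) -
      leaf_logmarg(nl + nr, sl + sr, tau2)
    lprior <- log(psplit(d)) + 2 * log(1 - psplit(d + 1)) - log(1 - psplit(d))
    par <- tr$parent[leaf]
    parent_was_nog <- !is.na(par) && par %in% cnt$nog
    n_nog_new <- length(cnt$nog) + 1L - as.integer(parent_was_nog)
    ltrans <- log(pp[["prune"]]) - log(p_grow_here) +
      log(length(cnt$leaves)) - log(n_nog_new)
    if (log(stats::runif(1)) < dll + lprior + ltrans) {
      a1 <- alloc_node(tr); tr <- a1$tree; lid <- a1$id
      a2 <- alloc_node(tr); tr <- a2$tree; rid <- a2$id
      tr$var[leaf] <- v; tr$cut[leaf] <- cut
      tr$left[leaf] <- lid; tr$right[leaf] <- rid
      for (id in c(lid, rid)) {
        tr$var[id] <- NA_integer_; tr$cut[id] <- NA_real_
        tr$left[id] <- NA_integer_; tr$right[id] <- NA_integer_
        tr$parent[id] <- leaf; tr$depth[id] <- tr$depth[leaf] + 1L
        tr$alive[id] <- TRUE; tr$mu[id] <- 0
      }
      tr$node_of[members] <- ifelse(goleft, lid, rid)
    }
    return(tr)
  }

  if (move == "prune") {
    if (length(cnt$nog) == 0) return(tr)
    nd <- if (length(cnt$nog) == 1) cnt$nog else sample(cnt$nog, 1)
    lid <- tr$left[nd]; rid <- tr$right[nd]
    ml <- which(tr$node_of == lid); mr <- which(tr$node_of == rid)
    sl <- sum(r[ml]); sr <- sum(r[mr])
    nl <- length(ml); nr <- length(mr)
    d <- tr$depth[nd]
    dll <- leaf_logmarg(nl + nr, sl + sr, tau2) -
      leaf_logmarg(nl, sl, tau2) - leaf_logmarg(nr, sr, tau2)
    lprior <- -(log(psplit(d)) + 2 * log(1 - psplit(d + 1)) - log(1 - psplit(d)))
    n_leaves_new <- length(cnt$leaves) - 1L
    p_grow_new <- if (n_leaves_new == 1) 1 else pp[["grow"]]
    ltrans <- log(p_grow_new) - log(pp[["prune"]]) +
      log(length(cnt$nog)) - log(n_leaves_new)
    if (log(stats::runif(1)) < dll + lprior + ltrans) {
      tr$node_of[c(ml, mr)] <- nd
      tr$var[nd] <- NA_integer_; tr$cut[nd] <- NA_real_
      tr$left[nd] <- NA_integer_; tr$right[nd] <- NA_integer_
      tr$alive[c(lid, rid)] <- FALSE
      tr$free <- c(tr$free, lid, rid)
    }
    return(tr)
  }

  # change: redraw the split rule of a no-grandchild internal node
  if (length(cnt$nog) == 0) return(tr)
  nd <- if (length(cnt$nog) == 1) cnt$nog else sample(cnt$nog, 1)
  lid <- tr$left[nd]; rid <- tr$right[nd]
  members <- which(tr$node_of == lid | tr$node_of == rid)
  v <- if (length(usable) == 1) usable else sample(usable, 1)
  cuts <- cutpoints[[v]]
  cut <- cuts[sample.int(length(cuts), 1)]
  goleft <- X[members, v] <= cut
  nl <- sum(goleft); nr <- length(members) - nl
  if (nl < cfg$node_min || nr < cfg$node_min) return(tr)
  sl <- sum(r[members[goleft]]); sr <- sum(r[members[!goleft]])
  ol <- tr$node_of[members] == lid
  sl0 <- sum(r[members[ol]]); sr0 <- sum(r[members[!ol]])
  dll <- leaf_logmarg(nl, sl, tau2) + leaf_logmarg(nr, sr, tau2) -
    leaf_logmarg(sum(ol), sl0, tau2) - leaf_logmarg(sum(!ol), sr0, tau2)
  if (log(stats::runif(1)) < dll) {
    tr$var[nd] <- v; tr$cut[nd] <- cut
    tr$node_of[members] <- ifelse(goleft, lid, rid)
  }
  tr
}

# Conjugate draw of all leaf values; returns tree and its fitted vector.
draw_leaf_values <- function(tr, r, tau2) {
  leaves <- which(tr$alive & is.na(tr$var))
  grp <- match(tr$node_of, leaves)
  s <- as.vector(rowsum(r, grp, reorder = TRUE))
  n <- tabulate(grp, nbins = length(leaves))
  post_var <- 1 / (n + 1 / tau2)
  tr$mu[leaves] <- stats::rnorm(length(leaves), s * post_var, sqrt(post_var))
  list(tree = tr, fit = tr$mu[tr$node_of])
}

# Serialize a tree into a compact preorder form for storage/prediction.
compact_tree <- function(tr) {
  ord <- integer(0)
  stack <- 1L
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    ord <- c(ord, nd)
    if (!is.na(tr$var[nd])) stack <- c(tr$left[nd], tr$right[nd], stack)
  }
  remap <- match(seq_along(tr$var), ord)
  list(var = tr$var[ord], cut = tr$cut[ord],
       left = remap[tr$left[ord]], right = remap[tr$right[ord]],
       mu = tr$mu[ord])
}

# Evaluate a compact tree on a covariate matrix.
tree_eval <- function(ct, X) {
  m <- nrow(X)
  node_of <- rep(1L, m)
  for (nd in seq_along(ct$var)) {
    if (is.na(ct$var[nd])) next
    at <- which(node_of == nd)
    if (!length(at)) next
    goleft <- X[at, ct$var[nd]] <= ct$cut[nd]
    node_of[at] <- ifelse(goleft, ct$left[nd], ct$right[nd])
  }
  ct$mu[node_of]
}

# Truncated-normal latent draw for the probit augmentation.
draw_latent <- function(total, y) {
  n <- length(y)
  u <- stats::runif(n)
  z <- numeric(n)
  pos <- y == 1
  p0 <- stats::pnorm(-total[pos])
  z[pos] <- pmax(total[pos] +
    stats::qnorm(pmin(pmax(p0 + u[pos] * (1 - p0), 1e-300), 1 - 1e-16)), 1e-10)
  pu <- stats::pnorm(-total[!pos])
  z[!pos] <- pmin(total[!pos] +
    stats::qnorm(pmin(pmax(u[!pos] * pu, 1e-300), 1 - 1e-16)), -1e-10)
  z
}

#' Fit a probit BART species distribution model
#'
#' Binary-outcome Bayesian additive regression trees with a probit link:
#' the latent Gaussian variable is augmented per observation (truncated
#' normal given the label), a sum of regularized trees models its mean, and
#' trees are updated one at a time by backfitting Metropolis-Hastings moves
#' (grow/prune/change) on their structure with conjugate leaf-value draws.
#' The noise standard deviation is fixed at 1, as the probit construction
#' requires; the latent mean is offset by `qnorm(mean(y))`.
#'
#' @param x numeric covariate matrix (rows = presence + pseudoabsence
#'   points), with column names.
#' @param y 0/1 labels (1 = presence); both classes must be present.
#' @param config a [bart_config()].
#' @return object of class `bart_sdm`: posterior tree-ensemble draws plus
#'   in-sample probability draws. Methods: [predict.bart_sdm()],
#'   [variable_importance()], `print`, `summary`, `fitted`, `residuals`,
#'   `plot`.
#' @seealso [evaluate_model()], [tss_threshold()], [select_covariates()]
#' @export
fit_bart <- function(x, y, config = bart_config()) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("x and y sizes differ")
  if (anyNA(X) || anyNA(y)) stop("missing values in the design")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  cutpoints <- lapply(seq_len(ncol(X)), function(j) {
    sv <- sort(unique(X[, j]))
    if (length(sv) < 2) return(numeric(0))
    mids <- (sv[-1] + sv[-length(sv)]) / 2
    if (length(mids) > config$n_cutpoints)
      mids <- mids[unique(round(seq(1, length(mids), length.out = config$n_cutpoints)))]
    mids
  })
  usable <- which(lengths(cutpoints) > 0)
  if (!length(usable)) stop("zero-variance design: no covariate can be split")

  n <- nrow(X); m <- config$n_trees
  tau2 <- (3 / (config$k * sqrt(m)))^2
  offset <- stats::qnorm(mean(y))
  n_burn <- floor(config$n_iterations * config$burn_in_fraction)
  n_keep <- config$n_iterations - n_burn

  with_seed(config$seed, {
    trees <- replicate(m, new_tree(n), simplify = FALSE)
    fits <- matrix(0, n, m)
    fhat <- rowSums(fits)
    z <- draw_latent(rep(offset, n), y)
    draws <- vector("list", n_keep)
    prob_draws <- matrix(NA_real_, n_keep, n)
    split_counts <- matrix(0, n_keep, ncol(X))
    for (it in seq_len(config$n_iterations)) {
      for (j in seq_len(m)) {
        r <- z - offset - (fhat - fits[, j])
        tr <- update_tree_structure(trees[[j]], X, r, cutpoints, usable,
                                    config, tau2)
        lv <- draw_leaf_values(tr, r, tau2)
        trees[[j]] <- lv$tree
        fhat <- fhat - fits[, j] + lv$fit
        fits[, j] <- lv$fit
      }
      total <- offset + fhat
      z <- draw_latent(total, y)
      if (it > n_burn) {
        kd <- it - n_burn
        cts <- lapply(trees, compact_tree)
        draws[[kd]] <- cts
        prob_draws[kd, ] <- stats::pnorm(total)
        vs <- unlist(lapply(cts, function(ct) ct$var))
        vs <- vs[!is.na(vs)]
        if (length(vs)) split_counts[kd, ] <- tabulate(vs, nbins = ncol(X))
      }
    }
    structure(list(draws = draws, prob_draws = prob_draws,
                   split_counts = split_counts, offset = offset,
                   covariate_names = colnames(X), y = y,
                   config = config, n_obs = n),
              class = "bart_sdm")
  })
}

#' Posterior prediction from a fitted probit BART model
#'
#' Evaluates every retained posterior draw of the tree ensemble on new
#' covariate data and summarizes the per-point posterior of the occurrence
#' probability by its mean and central 95% credible-interval width
#' (97.5th minus 2.5th percentile).
#'
#' @param object a fitted [fit_bart()] model.
#' @param newdata either a numeric matrix with the training covariate columns
#'   or a named list of [raster_grid()] covariate layers (a covariate stack).
#' @param thin_draws optional count: use only this many (evenly spaced)
#'   retained draws.
#' @param ... unused.
#' @return for matrix input, a list with `mean_probability`, `ci_width`
#'   (vectors) and `draws` (draw x point probability matrix); for raster
#'   input, a list with `mean_probability` and `ci_width` [raster_grid()]
#'   layers.
#' @export
predict.bart_sdm <- function(object, newdata, thin_draws = NULL, ...) {
  is_stack <- is.list(newdata) && !is.data.frame(newdata) &&
    inherits(newdata[[1]], "raster_grid")
  if (is_stack) {
    nms <- names(newdata)
    missing_cov <- setdiff(object$covariate_names, nms)
    if (length(missing_cov))
      stop("covariate stack is missing: ", paste(missing_cov, collapse = ", "))
    g0 <- newdata[[1]]
    X <- vapply(object$covariate_names,
                function(nm) as.vector(newdata[[nm]]$values),
                numeric(length(g0$values)))
  } else {
    X <- as.matrix(newdata)
    if (is.data.frame(newdata)) X <- data.matrix(newdata)
    missing_cov <- setdiff(object$covariate_names, colnames(X))
    if (length(missing_cov) && ncol(X) == length(object$covariate_names) &&
        is.null(colnames(X))) {
      colnames(X) <- object$covariate_names
      missing_cov <- character(0)
    }
    if (length(missing_cov))
      stop("newdata is missing covariates: ", paste(missing_cov, collapse = ", "))
    X <- X[, object$covariate_names, drop = FALSE]
  }
  keep <- seq_along(object$draws)
  if (!is.null(thin_draws) && thin_draws < length(keep))
    keep <- unique(round(seq(1, length(keep), length.out = thin_draws)))
  P <- matrix(NA_real_, length(keep), nrow(X))
  for (i in seq_along(keep)) {
    f <- object$offset
    for (ct in object$draws[[keep[i]]]) f <- f + tree_eval(ct, X)
    P[i, ] <- stats::pnorm(f)
  }
  mp <- colMeans(P)
  qs <- apply(P, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  ciw <- qs[2, ] - qs[1, ]
  if (is_stack) {
    g0 <- newdata[[1]]
    shape <- function(v, nm) raster_grid(matrix(v, nrow(g0$values), ncol(g0$values)),
                                         g0$xmin, g0$ymin, g0$cell_size, nm)
    list(mean_probability = shape(mp, "mean_probability"),
         ci_width = shape(ciw, "ci_width"))
  } else {
    list(mean_probability = mp, ci_width = ciw, draws = P)
  }
}

#' @export
fitted.bart_sdm <- function(object, ...) colMeans(object$prob_draws)

#' @export
residuals.bart_sdm <- function(object, ...) object$y - fitted(object)

#' @export
print.bart_sdm <- function(x, ...) {
  cat(sprintf("Probit BART occurrence model: %d trees, %d iterations (%d retained), %d observations, %d covariates\n",
              x$config$n_trees, x$config$n_iterations, length(x$draws),
              x$n_obs, length(x$covariate_names)))
  invisible(x)
}

#' @export
summary.bart_sdm <- function(object, ...) {
  p <- fitted(object)
  diag <- evaluate_model(p, object$y)
  imp <- variable_importance(object)
  out <- list(diagnostics = diag, importance = imp,
              n_draws = length(object$draws), config = object$config)
  class(out) <- "summary.bart_sdm"
  out
}

#' @export
print.summary.bart_sdm <- function(x, ...) {
  cat(sprintf("In-sample AUC %.3f, TSS %.3f at threshold %.3f (%d retained draws)\n",
              x$diagnostics$auc, x$diagnostics$tss, x$diagnostics$threshold,
              x$n_draws))
  cat("Covariate importance (% of split rules):\n")
  print(round(x$importance, 1))
  invisible(x)
}

#' @export
plot.bart_sdm <- function(x, ...) {
  p <- fitted(x)
  graphics::plot(p, x$y + stats::runif(length(x$y), -0.03, 0.03),
                 xlab = "posterior mean occurrence probability",
                 ylab = "label (jittered)", pch = 16,
                 col = grDevices::adjustcolor(ifelse(x$y == 1, "forestgreen", "grey40"), 0.6),
                 main = "Probit BART: in-sample calibration", ...)
  invisible(x)
}
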