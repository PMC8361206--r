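#' Pairwise cophenetic distances between tree tips
#'
#' Sum of branch lengths along the path between every pair of tips
#' (zero diagonal, symmetric).
#'
#' @param tree an `ape` "phylo" tree with unique tip labels.
#' @return symmetric matrix with tip labels as dimnames.
#' @export
cophenetic_distances <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  stats::cophenetic(tree)
}

#' Mean pairwise phylogenetic distance of a community
#'
#' Mean cophenetic distance over all unordered pairs of species present
#' (self-pairs excluded). Undefined (NA) for communities of fewer than two
#' species.
#'
#' @param community character vector of present species, or a logical/0-1
#'   vector over the columns of `distances`.
#' @param distances symmetric distance matrix with species dimnames, e.g.
#'   from [cophenetic_distances()].
#' @return mean pairwise distance (NA if < 2 species present).
#' @export
mpd <- function(community, distances) {
  idx <- if (is.character(community)) {
    miss <- setdiff(community, rownames(distances))
    if (length(miss)) stop("species missing from the distance matrix: ",
                           paste(miss, collapse = ", "))
    match(community, rownames(distances))
  } else which(as.logical(community))
  if (length(idx) < 2) return(NA_real_)
  d <- distances[idx, idx]
  mean(d[upper.tri(d)])
}

#' Standardized effect size of MPD under a taxon-shuffle null
#'
#' For every unit of a community matrix, compares observed MPD to the null
#' distribution obtained by shuffling the tip labels of the phylogenetic
#' distance matrix (richness held fixed): `SES = (obs - mean_null)/sd_null`
#' (population SD of the null). Under the sign convention adopted here,
#' positive and negative SES indicate phylogenetic clustering and
#' overdispersion respectively; note that this labelling is the reverse of
#' the NRI-style usage (NRI = -SES), so interpret signs with care.
#'
#' The null is exact (all tip subsets of the pool enumerated) when the pool
#' has at most `exact_limit` tips, otherwise Monte-Carlo with `n_null`
#' shuffles. The rank p-value is the lower-tail probability
#' `(# null <= obs + 1) / (n_null + 1)` (exact fraction when enumerated).
#' The shuffle pool defaults to the full set of tree tips (matching a
#' "randomize the tips of the phylogeny" null); `pool = "matrix"` restricts
#' it to the species observed in the matrix, which changes SES.
#'
#' @param matrix 0/1 unit x species community matrix (species in columns).
#' @param tree an `ape` "phylo" tree covering every matrix species.
#' @param n_null Monte-Carlo null draws (>= 1).
#' @param seed integer seed.
#' @param pool `"tree"` (default) or `"matrix"`.
#' @param exact_limit enumerate exhaustively when the pool is at most this
#'   many tips.
#' @return data.frame with one row per unit: richness, mpd_obs, null_mean,
#'   null_sd, ses, p_value, n_null (0 for exact), and a `flag` column
#'   ("ok", "undefined_sd", "too_few_species").
#' @export
ses_mpd <- function(matrix, tree, n_null = 999, seed = 1,
                    pool = c("tree", "matrix"), exact_limit = 7) {
  pool <- match.arg(pool)
  if (n_null < 1) stop("n_null must be >= 1")
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("unit_", seq_len(nrow(matrix)))
  D_full <- cophenetic_distances(tree)
  miss <- setdiff(colnames(matrix), rownames(D_full))
  if (length(miss))
    stop("species missing from tree: ", paste(miss, collapse = ", "))
  pool_sp <- if (pool == "tree") rownames(D_full) else colnames(matrix)
  D <- D_full[pool_sp, pool_sp]
  np <- length(pool_sp)
  obs_mpd <- apply(matrix, 1, function(row)
    mpd(colnames(matrix)[row > 0], D_full))
  rich <- rowSums(matrix > 0)
  exact <- np <= exact_limit
  ks <- sort(unique(rich[rich >= 2]))
  null_stats <- list()
  if (exact) {
    for (k in ks) {
      vals <- utils::combn(np, k, function(ix) mean(D[ix, ix][upper.tri(D[ix, ix])]))
      null_stats[[as.character(k)]] <- list(vals = vals)
    }
  } else {
    with_seed(seed, {
      perms <- replicate(n_null, sample.int(np), simplify = FALSE)
      for (k in ks) {
        # under a tip shuffle, a richness-k unit occupies the first k slots of
        # a permuted pool: a uniform k-subset
        vals <- vapply(perms, function(p) {
          ix <- p[seq_len(k)]
          d <- D[ix, ix]
          mean(d[upper.tri(d)])
        }, numeric(1))
        null_stats[[as.character(k)]] <- list(vals = vals)
      }
    })
  }
  out <- lapply(seq_len(nrow(matrix)), function(i) {
    k <- rich[i]
    if (k < 2) {
      return(data.frame(unit_id = rownames(matrix)[i], richness = k,
                        mpd_obs = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, ses = NA_real_, p_value = NA_real_,
                        n_null = if (exact) 0L else as.integer(n_null),
                        flag = "too_few_species", stringsAsFactors = FALSE))
    }
    vals <- null_stats[[as.character(k)]]$vals
    mu <- mean(vals)
    sdv <- sqrt(mean((vals - mu)^2))
    obs <- obs_mpd[i]
    ses <- if (sdv > 0) (obs - mu) / sdv else NA_real_
    pv <- if (exact) mean(vals <= obs + 1e-12)
          else (sum(vals <= obs + 1e-12) + 1) / (length(vals) + 1)
    data.frame(unit_id = rownames(matrix)[i], richness = k, mpd_obs = obs,
               null_mean = mu, null_sd = sdv, ses = ses, p_value = pv,
               n_null = if (exact) 0L else as.integer(n_null),
               flag = if (sdv > 0) "ok" else "undefined_sd",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
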