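#' Virtual species niche
#'
#' A niche is a logit-linear-quadratic response to the landscape covariates:
#' `logit(p) = intercept + sum_j (linear_j * x_j + quadratic_j * x_j^2)`.
#' Unimodal responses arise from negative quadratic terms; a quadratic of
#' `-w` with linear `2 w o` is a Gaussian-shaped response centred on optimum
#' `o` with width `1/sqrt(2 w)` (on the standardized covariate scale).
#'
#' @param species_id character label.
#' @param linear,quadratic per-covariate coefficients (equal length).
#' @param intercept logit-scale intercept.
#' @param prevalence_target optional fraction in (0, 1); when given, the
#'   intercept is recalibrated against a landscape so that the mean occurrence
#'   probability equals the target.
#' @return a `species_niche` object.
#' @export
species_niche <- function(species_id, linear, quadratic, intercept = 0,
                          prevalence_target = NULL) {
  if (length(linear) != length(quadratic))
    stop("linear and quadratic coefficient vectors must have equal length")
  if (!nzchar(species_id)) stop("species_id must be non-empty")
  if (!is.null(prevalence_target) &&
      (prevalence_target <= 0 || prevalence_target >= 1))
    stop("prevalence_target must be in (0, 1)")
  structure(list(species_id = species_id, linear = as.numeric(linear),
                 quadratic = as.numeric(quadratic),
                 intercept = intercept, prevalence_target = prevalence_target),
            class = "species_niche")
}

#' True occurrence probability surface of a niche
#'
#' @param niche a [species_niche()].
#' @param landscape a [generate_landscape()] result (or list of covariate
#'   [raster_grid()] layers).
#' @return a [raster_grid()] of probabilities.
#' @export
niche_probability <- function(niche, landscape) {
  covs <- if (!is.null(landscape$covariates)) landscape$covariates else landscape
  if (length(covs) != length(niche$linear))
    stop("coefficient vector length does not match landscape covariate count")
  eta <- niche$intercept
  for (j in seq_along(covs)) {
    x <- covs[[j]]$values
    eta <- eta + niche$linear[j] * x + niche$quadratic[j] * x^2
  }
  g <- covs[[1]]
  raster_grid(stats::plogis(eta), g$xmin, g$ymin, g$cell_size,
              paste0("p_", niche$species_id))
}

# Intercept search so that mean probability over the landscape hits the target.
calibrate_intercept <- function(niche, landscape, target) {
  f <- function(b0) {
    n2 <- niche; n2$intercept <- b0
    mean(niche_probability(n2, landscape)$values) - target
  }
  stats::uniroot(f, c(-50, 50), tol = 1e-8)$root
}

#' Generate virtual species and their phylogeny
#'
#' Simulates a pure-birth phylogeny and evolves per-covariate niche optima
#' along it under Brownian motion, blended with independent draws so that
#' `phylo_signal` tunes niche conservatism: at 1 the optima are fully
#' tree-structured, at 0 they are i.i.d. Each species gets a unimodal
#' (negative-quadratic) response on every covariate, with niche widths and
#' prevalence targets drawn per species; intercepts are calibrated so each
#' species attains its prevalence target on the supplied landscape.
#'
#' By default each species' intercept is set so that the occurrence
#' probability at its niche optimum equals `peak_suitability`; prevalence
#' (the landscape-mean probability) then emerges from niche widths and the
#' position of the optimum, varying realistically between narrow-niched
#' range-restricted and broad-niched widespread species. Presence/background
#' occurrence data carry no information about an absolute intercept, so this
#' breadth-driven construction keeps prevalence an identifiable target for
#' downstream models. Alternatively, `prevalence_range` draws an explicit
#' per-species prevalence target and calibrates the intercept to it.
#'
#' @param n_species number of species (>= 2).
#' @param phylo_signal niche conservatism in \[0, 1\].
#' @param landscape a [generate_landscape()] result.
#' @param seed integer seed.
#' @param peak_suitability occurrence probability at the niche optimum
#'   (default 0.9) when prevalence is emergent.
#' @param prevalence_range optional range; when given, per-species prevalence
#'   targets are drawn uniformly from it and intercepts are calibrated by
#'   search.
#' @param width_range range of niche-width parameters `w` (uniform; larger `w`
#'   means narrower response).
#' @return list with `niches` (list of [species_niche()]), `tree`
#'   (ape `phylo`, tips `sp01`, `sp02`, ...), and `optima`
#'   (species x covariate matrix).
#' @export
generate_species_and_tree <- function(n_species, phylo_signal, landscape,
                                      seed = 1, peak_suitability = 0.9,
                                      prevalence_range = NULL,
                                      width_range = c(0.2, 1.5)) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (phylo_signal < 0 || phylo_signal > 1)
    stop("phylo_signal must be in [0, 1]")
  p <- length(landscape$covariates)
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    scale01 <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    optima <- sapply(seq_len(p), function(j) {
      bm <- scale01(ape::rTraitCont(tree, model = "BM", sigma = 1))
      iid <- stats::rnorm(n_species)
      sqrt(phylo_signal) * bm + sqrt(1 - phylo_signal) * iid
    })
    optima <- matrix(optima, n_species, p,
                     dimnames = list(tree$tip.label, NULL))
    widths <- matrix(stats::runif(n_species * p, width_range[1], width_range[2]),
                     n_species, p)
    prev <- if (!is.null(prevalence_range))
      stats::runif(n_species, prevalence_range[1], prevalence_range[2])
    niches <- lapply(seq_len(n_species), function(i) {
      ni <- species_niche(tree$tip.label[i],
                          linear = 2 * widths[i, ] * optima[i, ],
                          quadratic = -widths[i, ],
                          prevalence_target = prev[i])
      ni$intercept <- if (is.null(prev))
        stats::qlogis(peak_suitability) - sum(widths[i, ] * optima[i, ]^2)
      else calibrate_intercept(ni, landscape, prev[i])
      ni
    })
    list(niches = niches, tree = tree, optima = optima)
  })
}
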