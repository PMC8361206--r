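#' Realize occurrence records and true state from niches
#'
#' Draws species occurrence points with sampling weight proportional to the
#' true occurrence probability times a multiplicative spatial bias field
#' (`exp(bias_strength * smooth field)`, constant when `bias_strength = 0`),
#' emulating unevenly collected museum/aggregator records. Also realizes the
#' ground truth: per-species probability surfaces and Bernoulli presence
#' grids.
#'
#' @param niches list of [species_niche()].
#' @param landscape a [generate_landscape()] result.
#' @param n_per_species points drawn per species (>= 1).
#' @param bias_strength >= 0; 0 disables sampling bias.
#' @param seed integer seed.
#' @return list with `occurrences` (data.frame species_id, x, y, provenance),
#'   and `true_state` (list: `probability`, `presence` — per-species
#'   [raster_grid()] lists).
#' @export
realize_occurrences <- function(niches, landscape, n_per_species,
                                bias_strength = 0, seed = 1) {
  if (n_per_species < 1) stop("n_per_species must be >= 1")
  if (bias_strength < 0) stop("bias_strength must be >= 0")
  g0 <- landscape$covariates[[1]]
  cs <- g0$cell_size
  d <- dim(g0$values)
  cc <- cell_centers(g0)
  with_seed(seed, {
    bias <- if (bias_strength > 0)
      exp(bias_strength * random_field(d[1], d[2], landscape$config$autocorr_range, cs))
    else matrix(1, d[1], d[2])
    prob <- lapply(niches, niche_probability, landscape = landscape)
    presence <- lapply(seq_along(niches), function(i) {
      p <- prob[[i]]$values
      raster_grid(matrix(as.numeric(stats::runif(length(p)) < p), d[1], d[2]),
                  g0$xmin, g0$ymin, cs, paste0("presence_", niches[[i]]$species_id))
    })
    occ <- lapply(seq_along(niches), function(i) {
      w <- as.vector(prob[[i]]$values * bias)
      if (all(w == 0))
        stop(sprintf("unsampleable species: %s has an all-zero probability surface",
                     niches[[i]]$species_id))
      cells <- sample.int(length(w), n_per_species, replace = TRUE, prob = w)
      data.frame(species_id = niches[[i]]$species_id,
                 x = cc$x[cells] + stats::runif(n_per_species, -0.5, 0.5) * cs,
                 y = cc$y[cells] + stats::runif(n_per_species, -0.5, 0.5) * cs,
                 provenance = "observed", stringsAsFactors = FALSE)
    })
    list(occurrences = do.call(rbind, occ),
         true_state = list(probability = prob, presence = presence))
  })
}
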