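#' Landscape configuration
#'
#' Describes a synthetic planar landscape: grid dimensions, cell size (km),
#' the autocorrelation range of the covariate fields (the scale of the
#' Gaussian smoothing kernel, km), and how many standardized covariate layers
#' to produce. The last covariate can be marked as a "microhabitat" axis: it
#' is generated with a much shorter autocorrelation range, emulating a
#' fine-grained environmental factor (soil moisture, local fire history) that
#' coarse Earth-observation covariates do not capture.
#'
#' @param n_rows,n_cols grid dimensions (>= 8).
#' @param cell_size cell edge, km.
#' @param autocorr_range smoothing scale, km (>= 0; 0 = white noise).
#' @param n_covariates number of covariate layers.
#' @param microhabitat logical; make the last covariate fine-grained.
#' @param seed integer seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 50, n_cols = 50, cell_size = 1,
                             autocorr_range = 10, n_covariates = 3,
                             microhabitat = FALSE, seed = 1) {
  if (n_rows < 8 || n_cols < 8) stop("landscape must be at least 8 x 8 cells")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (autocorr_range < 0) stop("autocorr_range must be >= 0")
  if (n_covariates < 1) stop("need at least one covariate")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, autocorr_range = autocorr_range,
                 n_covariates = as.integer(n_covariates),
                 microhabitat = isTRUE(microhabitat), seed = as.integer(seed)),
            class = "landscape_config")
}

# Gaussian-kernel smoothing of a matrix, range in km. Separable kernel applied
# by row/column weight matrices with edge renormalization.
smooth_field <- function(z, range_km, cell_size) {
  if (range_km <= 0) return(z)
  kmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * cell_size)
    w <- exp(-0.5 * (d / range_km)^2)
    sweep(w, 1, rowSums(w), "/")
  }
  kmat(nrow(z)) %*% z %*% t(kmat(ncol(z)))
}

# One standardized spatially autocorrelated field.
random_field <- function(n_rows, n_cols, range_km, cell_size) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- smooth_field(z, range_km, cell_size)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic landscape
#'
#' Produces standardized (mean 0, sd 1), spatially autocorrelated covariate
#' layers plus monthly minimum/maximum temperature and precipitation stacks
#' that emulate monthly Earth-observation climate inputs. The annual-mean
#' temperature surface follows covariate 1 and total precipitation follows
#' covariate 2 (when present), so bioclimatic summaries derived from the
#' climate stacks carry real information about the covariates that define
#' species niches.
#'
#' @param config a [landscape_config()].
#' @return list with elements `covariates` (list of [raster_grid()]),
#'   `tmin`, `tmax`, `precip` (lists of 12 monthly [raster_grid()] layers,
#'   degC and mm/month), and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  as_grid <- function(v, name) raster_grid(v, 0, 0, cs, name)
  with_seed(config$seed, {
    ranges <- rep(config$autocorr_range, config$n_covariates)
    if (config$microhabitat && config$n_covariates >= 2)
      ranges[config$n_covariates] <- min(1.5 * cs, config$autocorr_range)
    covs <- lapply(seq_len(config$n_covariates), function(j)
      as_grid(random_field(nr, nc, ranges[j], cs), paste0("cov", j)))

    c1 <- covs[[1]]$values
    c2 <- if (config$n_covariates >= 2) covs[[2]]$values
          else random_field(nr, nc, config$autocorr_range, cs)
    season <- cos(2 * pi * (1:12 - 7) / 12)  # peaks in July
    tmin <- vector("list", 12); tmax <- vector("list", 12); prec <- vector("list", 12)
    for (m in 1:12) {
      tavg <- 10 + 4 * c1 + 10 * season[m]
      e1 <- random_field(nr, nc, config$autocorr_range, cs)
      e2 <- random_field(nr, nc, config$autocorr_range, cs)
      e3 <- random_field(nr, nc, config$autocorr_range, cs)
      tmin[[m]] <- as_grid(tavg - 5 + 0.3 * e1, sprintf("tmin_%02d", m))
      tmax[[m]] <- as_grid(tavg + 5 + 0.3 * e2, sprintf("tmax_%02d", m))
      prec[[m]] <- as_grid(pmax(80 * (1 + 0.5 * c2) * (1 + 0.6 * season[m]) +
                                  10 * e3, 0), sprintf("precip_%02d", m))
    }
    list(covariates = covs, tmin = tmin, tmax = tmax, precip = prec,
         config = config)
  })
}
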