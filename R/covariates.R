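#' Derive the 19 bioclimatic covariates from monthly climate stacks
#'
#' Computes BIO1-BIO19 from 12 monthly minimum/maximum temperature layers
#' (degC) and 12 monthly precipitation layers (mm/month), using the
#' wrap-around quarter convention: quarters are all 12 contiguous 3-month
#' windows, including those spanning the year boundary (Dec-Jan-Feb etc.);
#' the wettest/driest/warmest/coldest quarter is the first window attaining
#' the extremum. Monthly mean temperature is `(tmin + tmax) / 2`.
#'
#' Definitions (cell-wise over the 12 monthly values): BIO1 mean of monthly
#' means; BIO2 mean diurnal range `mean(tmax - tmin)`; BIO3 isothermality
#' `100 * BIO2 / BIO7`; BIO4 temperature seasonality `100 * sd` (sample sd);
#' BIO5 max tmax; BIO6 min tmin; BIO7 `BIO5 - BIO6`; BIO8/BIO9 mean
#' temperature of the wettest/driest quarter; BIO10/BIO11 mean temperature of
#' the warmest/coldest quarter; BIO12 annual precipitation (sum); BIO13/BIO14
#' precipitation of the wettest/driest month; BIO15 precipitation seasonality
#' (coefficient of variation, percent); BIO16/BIO17 precipitation of the
#' wettest/driest quarter; BIO18/BIO19 precipitation of the warmest/coldest
#' quarter.
#'
#' @param tmin,tmax,precip lists of 12 monthly [raster_grid()] layers on one
#'   geometry.
#' @param bio15_denominator `"mean_plus_one"` (default) computes BIO15 as
#'   `100 * sd / (1 + mean)` — the guard against zero-precipitation cells used
#'   by the common bioclim tooling dialect — or `"mean"` for the plain
#'   coefficient of variation.
#' @return named list of 19 [raster_grid()] layers, `bio1` .. `bio19`.
#' @export
derive_bioclim <- function(tmin, tmax, precip,
                           bio15_denominator = c("mean_plus_one", "mean")) {
  bio15_denominator <- match.arg(bio15_denominator)
  if (length(tmin) != 12 || length(tmax) != 12 || length(precip) != 12)
    stop("need exactly 12 monthly layers of tmin, tmax and precip")
  do.call(stopifnot_same_geometry, c(tmin, tmax, precip))
  g0 <- tmin[[1]]
  n <- length(g0$values)
  as_mat <- function(lst)
    matrix(vapply(lst, function(g) as.vector(g$values), numeric(n)), n, 12)
  TN <- as_mat(tmin); TX <- as_mat(tmax); PR <- as_mat(precip)  # n x 12
  if (any(TX < TN)) stop("tmax < tmin in some cell/month")
  TA <- (TN + TX) / 2
  win <- lapply(1:12, function(m) ((m - 1):(m + 1)) %% 12 + 1)
  qtemp <- matrix(vapply(win, function(w) rowMeans(TA[, w, drop = FALSE]),
                         numeric(n)), n, 12)
  qprec <- matrix(vapply(win, function(w) rowSums(PR[, w, drop = FALSE]),
                         numeric(n)), n, 12)
  first_max <- function(M) max.col(M, ties.method = "first")
  first_min <- function(M) max.col(-M, ties.method = "first")
  pick <- function(M, idx) M[cbind(seq_len(n), idx)]
  rsd <- function(M) apply(M, 1, stats::sd)

  wetq <- first_max(qprec); dryq <- first_min(qprec)
  warmq <- first_max(qtemp); coldq <- first_min(qtemp)
  b <- list()
  b$bio1 <- rowMeans(TA)
  b$bio2 <- rowMeans(TX - TN)
  b$bio5 <- apply(TX, 1, max)
  b$bio6 <- apply(TN, 1, min)
  b$bio7 <- b$bio5 - b$bio6
  b$bio3 <- ifelse(b$bio7 > 0, 100 * b$bio2 / b$bio7, 0)
  b$bio4 <- 100 * rsd(TA)
  b$bio8 <- pick(qtemp, wetq)
  b$bio9 <- pick(qtemp, dryq)
  b$bio10 <- pick(qtemp, warmq)
  b$bio11 <- pick(qtemp, coldq)
  b$bio12 <- rowSums(PR)
  b$bio13 <- apply(PR, 1, max)
  b$bio14 <- apply(PR, 1, min)
  denom <- if (bio15_denominator == "mean_plus_one") 1 + rowMeans(PR) else rowMeans(PR)
  b$bio15 <- ifelse(denom != 0, 100 * rsd(PR) / denom, 0)
  b$bio16 <- pick(qprec, wetq)
  b$bio17 <- pick(qprec, dryq)
  b$bio18 <- pick(qprec, warmq)
  b$bio19 <- pick(qprec, coldq)

  b <- b[paste0("bio", 1:19)]
  lapply(stats::setNames(names(b), names(b)), function(nm)
    raster_grid(matrix(b[[nm]], nrow(g0$values), ncol(g0$values)),
                g0$xmin, g0$ymin, g0$cell_size, nm))
}

#' Leaf-area-index composites from a multi-year monthly series
#'
#' Forms the per-month climatology (mean across years for each calendar
#' month), then three composites summarizing the annual LAI cycle:
#' `cumulative` (sum of the 12 climatology layers), `minimum` (cell-wise
#' minimum) and `seasonality` (coefficient of variation, percent,
#' `100 * sd / mean` over the 12 climatology values; 0 where the mean is 0).
#'
#' @param monthly_lai list of monthly [raster_grid()] layers.
#' @param months integer vector of calendar months (1-12) labelling each
#'   layer; all 12 months must occur.
#' @return list with [raster_grid()] elements `cumulative`, `minimum`,
#'   `seasonality`.
#' @export
derive_lai_composites <- function(monthly_lai, months = rep(1:12, length.out = length(monthly_lai))) {
  if (length(months) != length(monthly_lai))
    stop("months must label every layer")
  if (!all(1:12 %in% months))
    stop("need at least one layer for each of the 12 calendar months")
  do.call(stopifnot_same_geometry, monthly_lai)
  g0 <- monthly_lai[[1]]
  n <- length(g0$values)
  M <- matrix(vapply(monthly_lai, function(g) as.vector(g$values), numeric(n)),
              n, length(monthly_lai))
  clim <- matrix(vapply(1:12, function(m)
    rowMeans(M[, months == m, drop = FALSE]), numeric(n)), n, 12)
  mu <- rowMeans(clim)
  s <- apply(clim, 1, stats::sd)
  out <- list(cumulative = rowSums(clim),
              minimum = apply(clim, 1, min),
              seasonality = ifelse(mu != 0, 100 * s / mu, 0))
  lapply(stats::setNames(names(out), names(out)), function(nm)
    raster_grid(matrix(out[[nm]], nrow(g0$values), ncol(g0$values)),
                g0$xmin, g0$ymin, g0$cell_size, paste0("lai_", nm)))
}

#' Downscale a raster layer by an integer factor
#'
#' Increases resolution by `factor`: each input cell becomes a
#' `factor x factor` block. `nearest` replicates cell values (preserving the
#' multiset of values); `bilinear` interpolates between the four surrounding
#' input cell centres (cells beyond the outermost centres are linearly
#' extrapolated), reproducing linear gradients exactly at output cell centres.
#'
#' @param layer a [raster_grid()].
#' @param factor integer >= 2.
#' @param method `"nearest"` or `"bilinear"`.
#' @return a [raster_grid()] with `factor`-times the rows and columns.
#' @export
downscale <- function(layer, factor, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (length(factor) != 1 || factor != round(factor) || factor < 2)
    stop("factor must be a single integer >= 2")
  factor <- as.integer(factor)
  v <- layer$values
  nr <- nrow(v); nc <- ncol(v)
  cs_out <- layer$cell_size / factor
  if (method == "nearest") {
    out <- v[rep(seq_len(nr), each = factor), rep(seq_len(nc), each = factor)]
  } else {
    # output cell-centre positions in input cell-index coordinates
    # (input centres sit at 1..n in this coordinate)
    pos <- function(n) (seq_len(n * factor) - 0.5) / factor + 0.5
    ri <- pos(nr); ci <- pos(nc)
    interp1 <- function(t, n) {
      if (n == 1L) return(list(lo = rep(1L, length(t)), w = rep(0, length(t))))
      lo <- pmin(pmax(floor(t), 1L), n - 1L)
      list(lo = lo, w = t - lo)
    }
    r <- interp1(ri, nr); cL <- interp1(ci, nc)
    rhi <- pmin(r$lo + 1L, nr)
    out <- matrix(0, nr * factor, nc * factor)
    for (j in seq_len(nc * factor)) {
      c0 <- cL$lo[j]; wc <- cL$w[j]
      colv <- v[, c0] * (1 - wc) + v[, pmin(c0 + 1L, nc)] * wc
      out[, j] <- colv[r$lo] * (1 - r$w) + colv[rhi] * r$w
    }
  }
  raster_grid(out, layer$xmin, layer$ymin, cs_out, layer$name)
}

#' Compare two raster layers: Schoener's D and Spearman correlation
#'
#' Schoener's D treats each layer as a spatial distribution: over the shared
#' valid (non-NA in both) cells, each layer is shifted to be non-negative
#' (minimum subtracted when negative) and normalized to sum to 1, then
#' `D = 1 - 0.5 * sum(|p_a - p_b|)`, ranging from 0 (no overlap) to 1
#' (identical distributions). Spearman's rank correlation is computed on the
#' raw paired values; it is undefined (NA, with a warning) when either layer
#' is constant.
#'
#' @param a,b [raster_grid()] layers on one geometry.
#' @return list with `schoener_d` and `spearman_rho`.
#' @export
compare_layers <- function(a, b) {
  stopifnot_same_geometry(a, b)
  va <- as.vector(a$values); vb <- as.vector(b$values)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 2) stop("need at least 2 shared valid cells")
  va <- va[ok]; vb <- vb[ok]
  normalize <- function(v) {
    if (min(v) < 0) v <- v - min(v)
    s <- sum(v)
    if (s == 0) stop("layer has zero total mass after shifting; cannot normalize")
    v / s
  }
  d <- 1 - 0.5 * sum(abs(normalize(va) - normalize(vb)))
  rho <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("Spearman correlation undefined for a constant layer; reported as NA")
    NA_real_
  } else suppressWarnings(stats::cor(va, vb, method = "spearman"))
  list(schoener_d = d, spearman_rho = rho)
}
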