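const_stack <- function(tmin_v, tmax_v, prec_v, n = 3) {
  list(tmin = lapply(rep(tmin_v, length.out = 12), function(v)
         raster_grid(matrix(v, n, n))),
       tmax = lapply(rep(tmax_v, length.out = 12), function(v)
         raster_grid(matrix(v, n, n))),
       precip = lapply(rep(prec_v, length.out = 12), function(v)
         raster_grid(matrix(v, n, n))))
}

test_that("constant climate series give the degenerate bioclim values", {
  s <- const_stack(10, 10, 100)
  b <- derive_bioclim(s$tmin, s$tmax, s$precip)
  expect_equal(unique(as.vector(b$bio1$values)), 10)
  expect_equal(unique(as.vector(b$bio4$values)), 0)
  expect_equal(unique(as.vector(b$bio12$values)), 1200)
  expect_equal(unique(as.vector(b$bio15$values)), 0)
  expect_true(all(b$bio5$values >= b$bio6$values))
})

test_that("bioclim matches the per-cell scalar oracle, seasonal case included", {
  tm <- c(-5, 0, 5, 10, 15, 20, 25, 20, 15, 10, 5, 0)
  s <- list(tmin = lapply(tm, function(v) raster_grid(matrix(v, 2, 2))),
            tmax = lapply(tm, function(v) raster_grid(matrix(v, 2, 2))),
            precip = lapply(seq(10, 120, 10), function(v)
              raster_grid(matrix(v, 2, 2))))
  b <- derive_bioclim(s$tmin, s$tmax, s$precip)
  expect_equal(as.vector(b$bio1$values)[1], 10)
  oracle <- bioclim_scalar(tm, tm, seq(10, 120, 10))
  got <- sapply(1:19, function(k) b[[paste0("bio", k)]]$values[1, 1])
  expect_equal(unname(got), oracle, tolerance = 1e-9)
})

test_that("bioclim equals the scalar oracle on random series and single cells", {
  set.seed(31)
  for (rep_i in 1:25) {
    tmin_v <- runif(12, -10, 15)
    tmax_v <- tmin_v + runif(12, 0, 15)
    prec_v <- runif(12, 0, 300)
    s <- list(tmin = lapply(tmin_v, function(v) raster_grid(matrix(v, 1, 1))),
              tmax = lapply(tmax_v, function(v) raster_grid(matrix(v, 1, 1))),
              precip = lapply(prec_v, function(v) raster_grid(matrix(v, 1, 1))))
    b <- derive_bioclim(s$tmin, s$tmax, s$precip)
    got <- sapply(1:19, function(k) b[[paste0("bio", k)]]$values[1, 1])
    expect_equal(unname(got), bioclim_scalar(tmin_v, tmax_v, prec_v),
                 tolerance = 1e-9)
    b2 <- derive_bioclim(s$tmin, s$tmax, s$precip,
                         bio15_denominator = "mean")
    expect_equal(b2$bio15$values[1, 1],
                 bioclim_scalar(tmin_v, tmax_v, prec_v, plus_one = FALSE)[15],
                 tolerance = 1e-9)
  }
})

test_that("bioclim rejects incomplete or inconsistent inputs", {
  s <- const_stack(5, 10, 50)
  expect_error(derive_bioclim(s$tmin[1:11], s$tmax, s$precip), "12 monthly")
  s_bad <- s
  s_bad$tmax[[3]] <- raster_grid(matrix(0, 3, 3))  # below tmin = 5
  expect_error(derive_bioclim(s$tmin, s_bad$tmax, s$precip), "tmax < tmin")
  s_geo <- s
  s_geo$precip[[1]] <- raster_grid(matrix(50, 4, 4))
  expect_error(derive_bioclim(s$tmin, s$tmax, s_geo$precip), "geometry")
})

test_that("LAI composites summarize the monthly climatology", {
  g <- function(v) raster_grid(matrix(v, 2, 2))
  const2 <- derive_lai_composites(lapply(rep(2, 12), g))
  expect_equal(unique(as.vector(const2$cumulative$values)), 24)
  expect_equal(unique(as.vector(const2$minimum$values)), 2)
  expect_equal(unique(as.vector(const2$seasonality$values)), 0)

  one_year <- derive_lai_composites(lapply(1:12, g))
  expect_equal(one_year$cumulative$values[1, 1], 78)
  expect_equal(one_year$minimum$values[1, 1], 1)
  expect_equal(one_year$seasonality$values[1, 1], 100 * sd(1:12) / mean(1:12))

  two_years <- derive_lai_composites(lapply(c(1:12, 1:12), g),
                                     months = rep(1:12, 2))
  for (nm in names(one_year))
    expect_equal(two_years[[nm]]$values, one_year[[nm]]$values)
  expect_error(derive_lai_composites(lapply(1:6, g), months = 1:6),
               "12 calendar months")
})

test_that("downscaling obeys shape, constancy, multiset and plane contracts", {
  const <- raster_grid(matrix(5, 4, 4))
  expect_true(all(downscale(const, 3)$values == 5))
  expect_equal(dim(downscale(raster_grid(matrix(1:16, 4, 4)), 2)$values),
               c(8L, 8L))
  expect_error(downscale(const, 2.5), "integer")
  expect_error(downscale(const, 1), "integer")

  set.seed(8)
  rnd <- raster_grid(matrix(rnorm(16), 4, 4))
  near <- downscale(rnd, 3, "nearest")
  expect_equal(sort(as.vector(near$values)),
               sort(rep(as.vector(rnd$values), 9)))

  plane <- raster_grid(matrix(0, 4, 4), cell_size = 2)
  cc_in <- cell_centers(plane)
  plane$values[cbind(cc_in$row, cc_in$col)] <- 2 * cc_in$x + 1.5 * cc_in$y - 1
  for (f in c(2, 3)) {
    d <- downscale(plane, f, "bilinear")
    cc <- cell_centers(d)
    expect_equal(d$values[cbind(cc$row, cc$col)],
                 2 * cc$x + 1.5 * cc$y - 1, tolerance = 1e-10)
  }
})

test_that("Schoener's D and Spearman comparisons behave per definition", {
  set.seed(9)
  a <- rand_grid(4)
  expect_equal(compare_layers(a, a)$schoener_d, 1)
  expect_equal(compare_layers(a, a)$spearman_rho, 1)

  g1 <- raster_grid(matrix(c(0.5, 0.5, 0, 0), 1))
  g2 <- raster_grid(matrix(c(0, 0.5, 0.5, 0), 1))
  expect_equal(compare_layers(g1, g2)$schoener_d, 0.5)

  d1 <- raster_grid(matrix(c(1, 1, 0, 0), 1))
  d2 <- raster_grid(matrix(c(0, 0, 1, 1), 1))
  expect_equal(compare_layers(d1, d2)$schoener_d, 0)

  # symmetry and invariance to positive rescaling
  b <- rand_grid(4)
  ab <- compare_layers(a, b)
  expect_equal(ab$schoener_d, compare_layers(b, a)$schoener_d)
  b3 <- b; b3$values <- b$values * 3
  expect_equal(compare_layers(a, b3)$schoener_d, ab$schoener_d,
               tolerance = 1e-12)

  const <- raster_grid(matrix(1, 4, 4))
  expect_warning(res <- compare_layers(a, const), "constant")
  expect_true(is.na(res$spearman_rho))
})
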