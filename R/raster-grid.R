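#' Georeferenced raster grid
#'
#' Lightweight planar raster container used throughout the package: a numeric
#' matrix plus an origin and a square cell size in km. Row 1 of the matrix is
#' the northern-most row; columns run west to east. Cells are centre-registered:
#' the centre of cell (row r, col c), 1-based, lies at
#' `x = xmin + (c - 0.5) * cell_size`, `y = ymax - (r - 0.5) * cell_size`.
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin,ymin coordinates (km) of the south-west corner of the grid.
#' @param cell_size cell edge length in km (> 0).
#' @param name optional layer name.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cell_size = 1, name = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cell_size = cell_size, name = name),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid %s: %d x %d cells, %.3g km/cell, extent x [%g, %g] y [%g, %g]\n",
              if (is.null(x$name)) "" else shQuote(x$name),
              d[1], d[2], x$cell_size,
              x$xmin, grid_xmax(x), x$ymin, grid_ymax(x)))
  v <- x$values
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d NA)\n",
              min(v, na.rm = TRUE), mean(v, na.rm = TRUE),
              max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

grid_xmax <- function(g) g$xmin + ncol(g$values) * g$cell_size
grid_ymax <- function(g) g$ymin + nrow(g$values) * g$cell_size

#' @rdname raster_grid
#' @param g a `raster_grid`.
#' @export
grid_dim <- function(g) dim(g$values)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stopifnot_same_geometry <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1]) {
    if (!same_geometry(gs[[1]], gs[[i]]))
      stop("raster layers do not share one geometry")
  }
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param g a `raster_grid`.
#' @return data.frame with columns row, col (1-based), x, y (km).
#' @export
cell_centers <- function(g) {
  d <- dim(g$values)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  data.frame(row = rc$row, col = rc$col,
             x = g$xmin + (rc$col - 0.5) * g$cell_size,
             y = grid_ymax(g) - (rc$row - 0.5) * g$cell_size)
}

#' Locate points on a grid
#'
#' Maps planar point coordinates to 1-based (row, col) cell indices using the
#' floor rule: a point exactly on an interior cell boundary belongs to the cell
#' to its south-east. Valid domain is `x in [xmin, xmax)`, `y in (ymin, ymax]`.
#'
#' @param g a `raster_grid`.
#' @param x,y point coordinates in km.
#' @return data.frame with columns row, col, cell (column-major linear index).
#' @export
cell_index <- function(g, x, y) {
  d <- dim(g$values)
  col <- floor((x - g$xmin) / g$cell_size) + 1L
  row <- floor((grid_ymax(g) - y) / g$cell_size) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  if (any(bad)) {
    stop(sprintf("point(s) outside raster extent: %s",
                 paste(sprintf("(%g, %g)", x[bad], y[bad]), collapse = ", ")))
  }
  data.frame(row = row, col = col, cell = row + (col - 1L) * d[1])
}

#' Extract raster values at points
#'
#' @inheritParams cell_index
#' @return numeric vector of cell values.
#' @export
extract_values <- function(g, x, y) {
  idx <- cell_index(g, x, y)
  g$values[idx$cell]
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of cell values, north first.
#'
#' @param g a `raster_grid`.
#' @param path file path.
#' @param digits significant digits written.
#' @return `read_asc` returns a `raster_grid`; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(g, path, digits = 10) {
  v <- g$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cell_size),
    "NODATA_value -9999"), con)
  v[is.na(v)] <- -9999
  writeLines(apply(v, 1, function(r) paste(signif(r, digits), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  v <- utils::read.table(path, skip = 6)
  v <- as.matrix(v)
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA_real_
  raster_grid(v, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              cell_size = val[["cellsize"]],
              name = sub("\\.asc$", "", basename(path)))
}

# Evaluate an expression with a private, restorable RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic substream seeds below 2^31, derived from a master seed.
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- utils::head(utf8ToInt(stage), 12)
  s <- (as.double(master) %% 2147483647)
  for (ch in h) s <- (s * 69069 + ch) %% 2147483647
  as.integer(s %% 2147480000 + 1)
}
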