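#' Thinning distance schedule
#'
#' Maps a species' record count to its spatial thinning distance: 1 km for
#' fewer than 100 records, 5 km for more than 10,000, and log-linear in
#' `log10(n)` between those anchors, clamped to \[1, 5\] km. The schedule
#' reflects the idea that densely sampled species need more aggressive
#' thinning to control sampling bias and spatial autocorrelation.
#'
#' @param n_records record count (>= 1).
#' @return thinning distance, km.
#' @export
thinning_distance_rule <- function(n_records) {
  if (any(n_records < 1)) stop("n_records must be >= 1")
  d <- 1 + 4 * (log10(n_records) - 2) / 2
  pmin(pmax(d, 1), 5)
}

#' Spatially thin occurrence records
#'
#' Per species, removes records until no two retained records are closer than
#' `distance` km (planar Euclidean). Uses randomized repeated elimination:
#' each pass repeatedly drops one record from those with the most too-close
#' neighbours (ties broken at random) until no conflicts remain; among
#' `n_repeats` passes the one retaining the most records wins (first such
#' pass on ties). Finding the true maximum is NP-hard; this is the standard
#' practical heuristic, deterministic given `seed`.
#'
#' @param table occurrence data.frame with columns species_id, x, y.
#' @param distance minimum separation, km (>= 0).
#' @param n_repeats randomized elimination passes per species.
#' @param seed integer seed.
#' @return thinned occurrence data.frame (original row order preserved).
#' @export
thin_occurrences <- function(table, distance, n_repeats = 25, seed = 1) {
  if (distance < 0) stop("distance must be >= 0")
  if (nrow(table) == 0) return(table)
  with_seed(seed, {
    keep_all <- logical(nrow(table))
    for (sp in unique(table$species_id)) {
      idx <- which(table$species_id == sp)
      keep_all[idx[thin_one(table$x[idx], table$y[idx], distance, n_repeats)]] <- TRUE
    }
    table[keep_all, , drop = FALSE]
  })
}

thin_one <- function(x, y, distance, n_repeats) {
  n <- length(x)
  if (n <= 1 || distance == 0) return(seq_len(n))
  close_m <- as.matrix(stats::dist(cbind(x, y))) < distance
  diag(close_m) <- FALSE
  if (!any(close_m)) return(seq_len(n))
  best <- integer(0)
  for (rep_i in seq_len(n_repeats)) {
    alive <- rep(TRUE, n)
    nn <- rowSums(close_m)
    while (any(nn[alive] > 0)) {
      cand <- which(alive & nn == max(nn[alive]))
      drop <- if (length(cand) == 1) cand else sample(cand, 1)
      alive[drop] <- FALSE
      nb <- which(close_m[drop, ] & alive)
      nn[nb] <- nn[nb] - 1L
      nn[drop] <- 0L
    }
    if (sum(alive) > length(best)) best <- which(alive)
  }
  best
}

#' Accessible area of a species
#'
#' Bounding box of the occurrence records expanded by `buffer_km` on every
#' side — a conservative representation of the region the species could have
#' dispersed through — optionally clipped to a landscape extent.
#'
#' @param table occurrence data.frame with columns x, y (one species).
#' @param buffer_km buffer beyond each bound, km.
#' @param landscape optional [generate_landscape()] result or [raster_grid()];
#'   when given, the box is clipped to its extent.
#' @return list with xmin, xmax, ymin, ymax (km).
#' @export
accessible_area <- function(table, buffer_km = 300, landscape = NULL) {
  if (nrow(table) == 0) stop("cannot build an accessible area from zero records")
  a <- list(xmin = min(table$x) - buffer_km, xmax = max(table$x) + buffer_km,
            ymin = min(table$y) - buffer_km, ymax = max(table$y) + buffer_km)
  if (!is.null(landscape)) {
    g <- if (inherits(landscape, "raster_grid")) landscape else landscape$covariates[[1]]
    a$xmin <- max(a$xmin, g$xmin); a$xmax <- min(a$xmax, grid_xmax(g))
    a$ymin <- max(a$ymin, g$ymin); a$ymax <- min(a$ymax, grid_ymax(g))
  }
  class(a) <- "accessible_area"
  a
}

#' Sample pseudoabsence (background) points
#'
#' Draws `n` points uniformly over the cells of `mask` whose centres fall
#' inside the accessible area, excluding cells that contain a presence
#' record. The pipeline default sets `n` equal to the number of presences.
#' Exclusion is at cell resolution: a sampled cell never coincides with a
#' presence cell. Cells are sampled without replacement; points sit at cell
#' centres.
#'
#' @param area an [accessible_area()].
#' @param n number of pseudoabsences.
#' @param presence_cells integer vector of (column-major) cell indices to
#'   exclude, e.g. from [cell_index()].
#' @param mask a [raster_grid()]; NA cells are unavailable.
#' @param seed integer seed.
#' @param species_id label attached to the output records.
#' @return occurrence data.frame (species_id, x, y, provenance =
#'   "pseudoabsence").
#' @export
sample_pseudoabsences <- function(area, n, presence_cells, mask, seed = 1,
                                  species_id = "species") {
  cc <- cell_centers(mask)
  cell <- cc$row + (cc$col - 1L) * nrow(mask$values)
  ok <- cc$x >= area$xmin & cc$x <= area$xmax &
        cc$y >= area$ymin & cc$y <= area$ymax &
        !is.na(mask$values[cell]) & !(cell %in% presence_cells)
  free <- which(ok)
  if (length(free) < n)
    stop(sprintf("only %d free cells available for %d pseudoabsences (short by %d)",
                 length(free), n, n - length(free)))
  with_seed(seed, {
    pick <- free[sample.int(length(free), n)]
    data.frame(species_id = species_id, x = cc$x[pick], y = cc$y[pick],
               provenance = "pseudoabsence", stringsAsFactors = FALSE)
  })
}
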