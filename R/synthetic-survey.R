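#' Survey design
#'
#' Nested plot-within-site survey, emulating an ecological observatory
#' layout: square sites of side `site_extent` km placed inside the landscape,
#' each containing `plots_per_site` point plots; species present in a plot's
#' cell are recorded with probability `detection_prob`.
#'
#' @param n_sites,plots_per_site counts (>= 1).
#' @param site_extent site square side, km.
#' @param detection_prob per-plot, per-species detection probability in
#'   \[0, 1\].
#' @param seed integer seed.
#' @return a `survey_design` list.
#' @export
survey_design <- function(n_sites = 8, plots_per_site = 6, site_extent = 5,
                          detection_prob = 0.8, seed = 1) {
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must be in [0, 1]")
  if (n_sites < 1 || plots_per_site < 1) stop("counts must be >= 1")
  if (site_extent <= 0) stop("site_extent must be positive")
  structure(list(n_sites = as.integer(n_sites),
                 plots_per_site = as.integer(plots_per_site),
                 site_extent = site_extent, detection_prob = detection_prob,
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Simulate a nested plot/site survey
#'
#' Places sites and plots, reads true presence at each plot's cell, thins by
#' the detection probability, and unions plot species lists into site lists.
#' Detection draws are coupled: the same design seed yields one uniform draw
#' per plot-species pair, compared against `detection_prob`, so raising the
#' detection probability can only add detections.
#'
#' @param true_state the `true_state` element of [realize_occurrences()]
#'   (per-species presence grids).
#' @param design a [survey_design()].
#' @return list with `plot_matrix`, `site_matrix` (0/1 unit x species
#'   matrices), `true_plot_matrix`, `true_site_matrix` (detection-free), and
#'   `hierarchy` (data.frame plot_id, site_id, x, y).
#' @export
generate_survey <- function(true_state, design) {
  stopifnot(inherits(design, "survey_design"))
  pres <- true_state$presence
  g0 <- pres[[1]]
  species <- sub("^presence_", "", vapply(pres, function(g) g$name, ""))
  ext_x <- c(g0$xmin, grid_xmax(g0)); ext_y <- c(g0$ymin, grid_ymax(g0))
  half <- design$site_extent / 2
  if (diff(ext_x) < design$site_extent || diff(ext_y) < design$site_extent)
    stop("site_extent exceeds the landscape extent")
  with_seed(design$seed, {
    sx <- stats::runif(design$n_sites, ext_x[1] + half, ext_x[2] - half)
    sy <- stats::runif(design$n_sites, ext_y[1] + half, ext_y[2] - half)
    n_plots <- design$n_sites * design$plots_per_site
    site_of <- rep(seq_len(design$n_sites), each = design$plots_per_site)
    px <- sx[site_of] + stats::runif(n_plots, -half, half)
    py <- sy[site_of] + stats::runif(n_plots, -half, half)
    # keep plots strictly inside the valid point domain [xmin, xmax) x (ymin, ymax]
    eps <- 1e-9 * g0$cell_size
    px <- pmin(pmax(px, ext_x[1]), ext_x[2] - eps)
    py <- pmin(pmax(py, ext_y[1] + eps), ext_y[2])
    u <- matrix(stats::runif(n_plots * length(species)), n_plots, length(species))

    truth <- sapply(pres, function(g) extract_values(g, px, py))
    truth <- matrix(truth, n_plots, length(species))
    obs <- truth * (u <= design$detection_prob)
    plot_ids <- sprintf("plot_%03d", seq_len(n_plots))
    site_ids <- sprintf("site_%02d", site_of)
    dimnames(obs) <- dimnames(truth) <- list(plot_ids, species)
    hierarchy <- data.frame(plot_id = plot_ids, site_id = site_ids,
                            x = px, y = py, stringsAsFactors = FALSE)
    list(plot_matrix = obs,
         site_matrix = sites_from_plots(obs, hierarchy),
         true_plot_matrix = truth,
         true_site_matrix = sites_from_plots(truth, hierarchy),
         hierarchy = hierarchy)
  })
}

#' Union plot rows of a community matrix into site rows
#'
#' @param plot_matrix unit x species incidence (or probability) matrix with
#'   plot ids as row names.
#' @param hierarchy data.frame with columns plot_id, site_id.
#' @param fun aggregation over member plots (default column-wise max, i.e.
#'   incidence union).
#' @return site x species matrix.
#' @export
sites_from_plots <- function(plot_matrix, hierarchy, fun = max) {
  if (!all(rownames(plot_matrix) %in% hierarchy$plot_id))
    stop("orphan plot(s): not present in the hierarchy table")
  sid <- hierarchy$site_id[match(rownames(plot_matrix), hierarchy$plot_id)]
  sites <- sort(unique(sid))
  out <- t(vapply(sites, function(s)
    apply(plot_matrix[sid == s, , drop = FALSE], 2, fun),
    numeric(ncol(plot_matrix))))
  dimnames(out) <- list(sites, colnames(plot_matrix))
  out
}
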