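#' Per-species prediction set
#'
#' Bundles each species' posterior mean probability layer, its binary layer
#' at the TSS-maximizing threshold, the threshold itself, and the
#' credible-interval-width layer, on one shared geometry — the input to every
#' stacking procedure.
#'
#' @param species character vector of species ids.
#' @param mean_probability,binary,ci_width named lists of [raster_grid()]
#'   layers (one per species; `binary`/`ci_width` optional for purely
#'   probabilistic work).
#' @param thresholds named numeric vector of binarization thresholds.
#' @return a `species_prediction_set`.
#' @export
species_prediction_set <- function(species, mean_probability, binary = NULL,
                                   thresholds = NULL, ci_width = NULL) {
  stopifnot(length(mean_probability) == length(species))
  names(mean_probability) <- species
  do.call(stopifnot_same_geometry, unname(mean_probability))
  for (lst in list(binary, ci_width)) if (!is.null(lst)) {
    stopifnot(length(lst) == length(species))
    do.call(stopifnot_same_geometry, c(list(mean_probability[[1]]), unname(lst)))
  }
  if (!is.null(binary)) names(binary) <- species
  if (!is.null(ci_width)) names(ci_width) <- species
  if (!is.null(thresholds)) names(thresholds) <- species
  structure(list(species = species, mean_probability = mean_probability,
                 binary = binary, thresholds = thresholds,
                 ci_width = ci_width),
            class = "species_prediction_set")
}

pred_matrix <- function(preds, what, units = NULL) {
  layers <- preds[[what]]
  if (is.null(layers)) stop(sprintf("prediction set has no '%s' layers", what))
  if (is.null(units)) {
    M <- vapply(layers, function(g) as.vector(g$values),
                numeric(length(layers[[1]]$values)))
    rownames(M) <- paste0("cell_", seq_len(nrow(M)))
  } else {
    M <- vapply(layers, function(g) extract_values(g, units$x, units$y),
                numeric(nrow(units)))
    M <- matrix(M, nrow(units), length(layers))
    rownames(M) <- units$unit_id
  }
  colnames(M) <- preds$species
  M
}

#' Extract per-unit species vectors from a prediction set
#'
#' Reads the probability and (when present) binary value of the raster cell
#' containing each unit point (cell-centre registration; points on interior
#' cell boundaries fall in the cell to their south-east).
#'
#' @param preds a [species_prediction_set()].
#' @param units data.frame with columns unit_id, x, y.
#' @return list with `probability` and `binary` unit x species matrices
#'   (`binary` NULL when absent from the set).
#' @export
extract_at_units <- function(preds, units) {
  stopifnot(all(c("unit_id", "x", "y") %in% names(units)))
  list(probability = pred_matrix(preds, "mean_probability", units),
       binary = if (!is.null(preds$binary)) pred_matrix(preds, "binary", units))
}

new_assemblage <- function(composition, type) {
  structure(list(unit_ids = rownames(composition), composition = composition,
                 richness = rowSums(composition), type = type),
            class = "assemblage_prediction")
}

#' @export
print.assemblage_prediction <- function(x, ...) {
  cat(sprintf("assemblage_prediction (%s): %d units x %d species, mean richness %.2f\n",
              x$type, nrow(x$composition), ncol(x$composition),
              mean(x$richness)))
  invisible(x)
}

#' Stack binary predictions (bS-SDM)
#'
#' Assemblage composition is the per-unit binary species vector; richness is
#' its sum.
#'
#' @param preds a [species_prediction_set()] with binary layers.
#' @param units optional data.frame (unit_id, x, y); default: every grid
#'   cell.
#' @return an `assemblage_prediction` of type "binary".
#' @export
stack_binary <- function(preds, units = NULL) {
  new_assemblage(pred_matrix(preds, "binary", units), "binary")
}

#' Stack probability predictions (pS-SDM)
#'
#' Richness is the per-unit sum of occurrence probabilities (the expected
#' richness); composition is kept as the probability vector and consumed
#' probabilistically by the evaluation stage.
#'
#' @inheritParams stack_binary
#' @return an `assemblage_prediction` of type "probability".
#' @export
stack_probability <- function(preds, units = NULL) {
  M <- pred_matrix(preds, "mean_probability", units)
  if (any(M < 0 | M > 1)) stop("probabilities outside [0, 1]")
  new_assemblage(M, "probability")
}

#' Stack with the probability ranking rule (cS-SDM)
#'
#' Emulates an ecological assembly rule: within each unit the species are
#' ranked by occurrence probability and the top `k` are marked present,
#' where `k` is that unit's observed-richness constraint. Ties are broken by
#' the fixed species order of the prediction set (alphabetical by default),
#' or at random when `tie_seed` is given.
#'
#' @inheritParams stack_binary
#' @param richness_constraints per-unit non-negative integer vector (recycled
#'   if length 1), ordered as the units.
#' @param tie_seed optional seed for randomized tie-breaking.
#' @return an `assemblage_prediction` of type "prr".
#' @export
stack_constrained_prr <- function(preds, richness_constraints, units = NULL,
                                  tie_seed = NULL) {
  M <- pred_matrix(preds, "mean_probability", units)
  k <- rep_len(richness_constraints, nrow(M))
  if (any(k < 0)) stop("richness constraints must be >= 0")
  alpha_rank <- rank(colnames(M), ties.method = "first")
  out <- M * 0
  with_seed(tie_seed, {
    for (i in seq_len(nrow(M))) {
      ki <- min(k[i], ncol(M))
      if (ki == 0) next
      tie <- if (is.null(tie_seed)) alpha_rank else sample(ncol(M))
      top <- order(-M[i, ], tie)[seq_len(ki)]
      out[i, top] <- 1
    }
  })
  new_assemblage(out, "prr")
}

#' Aggregate a plot-level assemblage prediction to sites
#'
#' Binary and PRR compositions are unioned species-wise (max over member
#' plots); probabilities are aggregated species-wise by max — the
#' probability that the species occurs in at least its best member plot
#' (configurable to the independence rule `1 - prod(1 - p)`).
#'
#' @param assemblage a plot-level `assemblage_prediction`.
#' @param hierarchy data.frame with columns plot_id, site_id covering every
#'   unit.
#' @param prob_rule `"max"` (default) or `"one_minus_prod"`.
#' @return a site-level `assemblage_prediction`.
#' @export
aggregate_to_sites <- function(assemblage, hierarchy,
                               prob_rule = c("max", "one_minus_prod")) {
  prob_rule <- match.arg(prob_rule)
  fun <- if (assemblage$type == "probability" && prob_rule == "one_minus_prod")
    function(p) 1 - prod(1 - p) else max
  M <- sites_from_plots(assemblage$composition, hierarchy, fun)
  new_assemblage(M, assemblage$type)
}

#' Stacked prediction uncertainty
#'
#' Per-cell sum of the per-species credible-interval widths: the total
#' posterior spread the stack carries into a cell's richness prediction.
#'
#' @param preds a [species_prediction_set()] with ci_width layers.
#' @return a [raster_grid()].
#' @export
stack_uncertainty <- function(preds) {
  if (is.null(preds$ci_width)) stop("prediction set has no ci_width layers")
  g0 <- preds$ci_width[[1]]
  v <- Reduce(`+`, lapply(preds$ci_width, function(g) g$values))
  raster_grid(v, g0$xmin, g0$ymin, g0$cell_size, "stacked_uncertainty")
}
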