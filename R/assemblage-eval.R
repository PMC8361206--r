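#' Confusion cells between observed and predicted species vectors
#'
#' For binary predictions these are the familiar contingency counts over
#' species: `a` both present, `b` predicted only, `c` observed only, `d`
#' both absent. For probabilistic predictions (pS-SDM) the cells are their
#' expectations under independent Bernoulli predictions:
#' `a = sum(p)` over observed-present species, `c = sum(1 - p)` over
#' observed-present, `b = sum(p)` over observed-absent, `d = sum(1 - p)`
#' over observed-absent. In both cases `a + b + c + d` equals the number of
#' species.
#'
#' @param observed 0/1 vector.
#' @param predicted 0/1 or \[0, 1\] vector of equal length.
#' @return list with `a`, `b`, `c`, `d`.
#' @export
confusion_cells <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted vectors differ in length")
  if (length(observed) < 1) stop("need at least one species")
  if (!all(observed %in% c(0, 1))) stop("observed vector must be 0/1")
  if (any(predicted < 0 | predicted > 1)) stop("predictions must lie in [0, 1]")
  pres <- observed == 1
  list(a = sum(predicted[pres]), c = sum(1 - predicted[pres]),
       b = sum(predicted[!pres]), d = sum(1 - predicted[!pres]))
}

#' Species-richness deviation
#'
#' Absolute deviation of predicted from observed richness, divided by the
#' maximum observed richness across the evaluation units — a scale-free
#' accuracy measure (0 is perfect).
#'
#' @param obs_richness,pred_richness unit richness values.
#' @param max_observed_richness positive normalizer (the survey-wide maximum
#'   observed richness).
#' @return ratio >= 0.
#' @export
sr_deviation <- function(obs_richness, pred_richness, max_observed_richness) {
  if (max_observed_richness <= 0) stop("max_observed_richness must be > 0")
  abs(pred_richness - obs_richness) / max_observed_richness
}

#' Species-richness change
#'
#' Signed `predicted - observed` richness: negative values are species lost
#' (underprediction), positive are gained (overprediction).
#'
#' @inheritParams sr_deviation
#' @return signed difference.
#' @export
sr_change <- function(obs_richness, pred_richness) {
  pred_richness - obs_richness
}

#' Composition metrics from confusion cells
#'
#' Prediction success `(a + d) / (a + b + c + d)`; TSS
#' `a/(a + c) + d/(b + d) - 1`; Sorensen similarity `2a / (2a + b + c)`.
#' When a denominator degenerates (no observed presences, or no observed
#' absences, or an empty union for Sorensen) the affected metric is NA with
#' a warning.
#'
#' @param cells a [confusion_cells()] result.
#' @return list with `prediction_success`, `tss`, `sorensen`.
#' @export
composition_metrics <- function(cells) {
  a <- cells$a; b <- cells$b; c <- cells$c; d <- cells$d
  n <- a + b + c + d
  if (n <= 0) stop("all confusion cells are zero")
  success <- (a + d) / n
  tss <- if (a + c == 0 || b + d == 0) {
    warning("TSS undefined: one observed class is empty")
    NA_real_
  } else a / (a + c) + d / (b + d) - 1
  sor <- if (2 * a + b + c == 0) {
    warning("Sorensen undefined: empty observed and predicted assemblages")
    NA_real_
  } else 2 * a / (2 * a + b + c)
  list(prediction_success = success, tss = tss, sorensen = sor)
}

#' Evaluate assemblage predictions against observations
#'
#' Per evaluation unit, computes SR deviation, SR change, prediction
#' success, TSS and the Sorensen index between the observed community matrix
#' and an assemblage prediction, plus mean and SD summaries. Species columns
#' are outer-joined with zero fill (reported via a message). Richness
#' metrics (SR deviation/change) are skipped for PRR predictions, whose
#' richness is constrained by the observed data.
#'
#' @param observed 0/1 unit x species matrix (unit ids as row names).
#' @param predicted an `assemblage_prediction` (see [stack_binary()] and
#'   friends) or a unit x species matrix.
#' @param scale label recorded in the output (e.g. "plot", "site").
#' @param max_observed_richness normalizer for SR deviation; default the
#'   maximum observed unit richness.
#' @return list of class `evaluation_report`: `per_unit` data.frame and
#'   `summary` (mean, sd per metric), plus `scale` and `type`.
#' @export
evaluate_assemblages <- function(observed, predicted, scale = "unit",
                                 max_observed_richness = NULL) {
  type <- if (inherits(predicted, "assemblage_prediction")) predicted$type else "binary"
  P <- if (inherits(predicted, "assemblage_prediction")) predicted$composition else predicted
  units <- intersect(rownames(observed), rownames(P))
  if (!length(units)) stop("no shared units between observed and predicted")
  all_sp <- union(colnames(observed), colnames(P))
  fill <- function(M) {
    miss <- setdiff(all_sp, colnames(M))
    if (length(miss)) {
      message(sprintf("outer join: zero-filling %d species column(s): %s",
                      length(miss), paste(miss, collapse = ", ")))
      M <- cbind(M, matrix(0, nrow(M), length(miss),
                           dimnames = list(rownames(M), miss)))
    }
    M[, all_sp, drop = FALSE]
  }
  O <- fill(observed)[units, , drop = FALSE]
  P <- fill(P)[units, , drop = FALSE]
  if (is.null(max_observed_richness)) max_observed_richness <- max(rowSums(O))
  skip_sr <- type == "prr"
  rows <- lapply(seq_along(units), function(i) {
    cm <- suppressWarnings(composition_metrics(confusion_cells(O[i, ], P[i, ])))
    data.frame(unit_id = units[i],
               obs_richness = sum(O[i, ]), pred_richness = sum(P[i, ]),
               sr_deviation = if (skip_sr) NA_real_ else
                 sr_deviation(sum(O[i, ]), sum(P[i, ]), max_observed_richness),
               sr_change = if (skip_sr) NA_real_ else
                 sr_change(sum(O[i, ]), sum(P[i, ])),
               prediction_success = cm$prediction_success,
               tss = cm$tss, sorensen = cm$sorensen,
               stringsAsFactors = FALSE)
  })
  per_unit <- do.call(rbind, rows)
  metrics <- c("sr_deviation", "sr_change", "prediction_success", "tss", "sorensen")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_unit[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_unit[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_unit = per_unit, summary = summ, scale = scale,
                 type = type),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Assemblage evaluation (%s predictions, %s scale, %d units):\n",
              x$type, x$scale, nrow(x$per_unit)))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}
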