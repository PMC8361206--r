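#' Read and write occurrence tables
#'
#' CSV with columns species_id, x, y and optionally provenance
#' (observed/pseudoabsence).
#'
#' @param table occurrence data.frame.
#' @param path file path.
#' @return `read_occurrences` returns the data.frame; writers return `path`
#'   invisibly.
#' @export
write_occurrences <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species_id, x, y")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates in occurrence table")
  df
}

#' Read and write community matrices
#'
#' CSV with a `unit_id` first column and one column per species.
#'
#' @param matrix unit x species matrix with row names.
#' @param path file path.
#' @return `read_community_matrix` returns a matrix; the writer returns
#'   `path` invisibly.
#' @export
write_community_matrix <- function(matrix, path) {
  df <- data.frame(unit_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
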