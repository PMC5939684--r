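#' @importFrom rlang abort warn %||%
#' @keywords internal
stop_mirlag <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mirlag_error")
}

# TRUE for a wide expression/detection tibble: feature_id + >=1 sample column
is_feature_table <- function(x) {
  is.data.frame(x) && ncol(x) >= 2 && names(x)[1] == "feature_id"
}

assert_feature_table <- function(x, what = "expression table") {
  if (!is_feature_table(x)) {
    stop_mirlag("%s must be a data frame with a `feature_id` first column and >=1 sample column", what)
  }
  if (anyDuplicated(x$feature_id) > 0) {
    stop_mirlag("duplicate feature ids in %s: %s", what,
                paste(unique(x$feature_id[duplicated(x$feature_id)])[1:3], collapse = ", "))
  }
  invisible(x)
}

sample_cols <- function(x) setdiff(names(x), "feature_id")

#' Convert between wide feature tables and numeric matrices
#'
#' `expr_matrix()` extracts the signal values of a wide expression tibble as
#' a features-by-samples numeric matrix (feature ids as rownames);
#' `matrix_to_tbl()` is its inverse.
#'
#' @param x A wide expression tibble (`feature_id` + sample columns).
#' @return `expr_matrix()` a numeric matrix; `matrix_to_tbl()` a wide
#'   tibble.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[, sample_cols(x), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

#' @param m A numeric matrix, features in rows, samples in columns.
#' @param feature_ids Feature identifiers (defaults to the rownames).
#' @rdname expr_matrix
#' @export
matrix_to_tbl <- function(m, feature_ids = rownames(m)) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(feature_id = feature_ids), out)
}
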