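#' Remove undetected and off-species features
#'
#' Mirrors the array-level filtering step: features not detected (absent) in
#' every array are removed, as are features not annotated to the target
#' species when an annotation is supplied. A feature present in even a
#' single array is retained. Feature order is preserved and the operation is
#' idempotent.
#'
#' @param expr Wide expression tibble.
#' @param calls Matching wide detection tibble (`"P"`/`"A"`).
#' @param species_annotation Optional tibble (`feature_id`, `species`).
#' @param keep_species Species label to retain when an annotation is given.
#' @return The filtered expression tibble.
#' @export
filter_undetected <- function(expr, calls, species_annotation = NULL,
                              keep_species = "mouse") {
  assert_feature_table(expr)
  assert_feature_table(calls, "detection table")
  if (!identical(dim(expr), dim(calls)) ||
      !identical(expr$feature_id, calls$feature_id) ||
      !identical(sample_cols(expr), sample_cols(calls))) {
    stop_mirlag("expression and detection tables must have identical shape and ids")
  }
  present <- rowSums(as.matrix(calls[, sample_cols(calls)]) == "P") >= 1
  keep <- present
  if (!is.null(species_annotation)) {
    sp <- species_annotation$species[match(expr$feature_id, species_annotation$feature_id)]
    keep <- keep & !is.na(sp) & sp == keep_species
  }
  expr[keep, , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's value distribution onto the common across-sample
#' mean of sorted vectors, preserving within-sample rank order. Ties within
#' a sample receive the mean of the quantile values they span (the dense
#' variant). Applied per platform: normalize the miRNA and mRNA matrices
#' separately.
#'
#' @param expr Wide expression tibble with no missing values.
#' @return The normalized expression tibble, same shape.
#' @export
quantile_normalize <- function(expr) {
  assert_feature_table(expr)
  m <- expr_matrix(expr)
  if (anyNA(m)) stop_mirlag("missing values are not allowed in quantile normalization")
  if (ncol(m) < 1) stop_mirlag("need >= 1 sample")
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(norm) <- dimnames(m)
  matrix_to_tbl(norm, expr$feature_id)
}

#' Subset detection calls to the features of an expression table
#'
#' Convenience for keeping a calls table aligned after filtering.
#'
#' @param calls Wide detection tibble.
#' @param expr Wide expression tibble whose features to keep.
#' @return The aligned detection tibble.
#' @export
align_calls <- function(calls, expr) {
  assert_feature_table(calls, "detection table")
  calls[match(expr$feature_id, calls$feature_id), , drop = FALSE]
}
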