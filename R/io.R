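#' Decode sample identifiers into metadata
#'
#' Sample columns of expression and detection tables are named
#' `<genotype>_<timepoint>_<replicate>`, e.g. `rd10_P15_2`. This parses that
#' encoding into a metadata tibble, erroring on malformed identifiers.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @return A tibble with columns `sample_id`, `genotype`, `timepoint`,
#'   `replicate` (integer).
#' @examples
#' parse_sample_ids(c("rd10_P15_2", "WT_P13_1"))
#' @export
parse_sample_ids <- function(sample_ids) {
  m <- stringr::str_match(sample_ids, "^([^_]+)_([^_]+)_([0-9]+)$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop_mirlag("malformed sample id(s): %s (expected <genotype>_<timepoint>_<rep>)",
                paste(sample_ids[bad][1:min(3, sum(bad))], collapse = ", "))
  }
  tibble::tibble(
    sample_id = sample_ids,
    genotype  = m[, 2],
    timepoint = m[, 3],
    replicate = as.integer(m[, 4])
  )
}

#' Extract sample metadata from a wide feature table
#'
#' @param x A wide expression or detection tibble (`feature_id` + sample
#'   columns).
#' @return A metadata tibble, one row per sample column.
#' @export
sample_metadata <- function(x) {
  assert_feature_table(x)
  parse_sample_ids(sample_cols(x))
}

#' Read and write feature-by-sample expression tables
#'
#' TSV dialect: first column `feature_id`, remaining columns one per sample,
#' sample ids encoded `<genotype>_<timepoint>_<rep>`. Values are linear-scale,
#' non-negative signals.
#'
#' @param path File path.
#' @return `read_expression_table()` returns a wide tibble.
#' @export
read_expression_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (names(x)[1] != "feature_id") stop_mirlag("first column must be `feature_id`")
  assert_feature_table(x)
  parse_sample_ids(sample_cols(x)) # validates the encoding
  vals <- expr_matrix(x)
  if (anyNA(vals)) stop_mirlag("non-numeric or missing cells in %s", path)
  if (any(vals < 0)) stop_mirlag("negative signal values in %s", path)
  x
}

#' @param x A wide expression tibble.
#' @rdname read_expression_table
#' @export
write_expression_table <- function(x, path) {
  assert_feature_table(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write detection-call tables
#'
#' Same layout as expression tables, with cells in `{P, A}`
#' (present / absent).
#'
#' @param path File path.
#' @return A wide tibble of `"P"`/`"A"` calls.
#' @export
read_detection_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (names(x)[1] != "feature_id") stop_mirlag("first column must be `feature_id`")
  assert_feature_table(x, "detection table")
  vals <- as.matrix(x[, sample_cols(x)])
  if (!all(vals %in% c("P", "A"))) stop_mirlag("detection calls must be 'P' or 'A'")
  x
}

#' @param x A wide detection tibble.
#' @rdname read_detection_table
#' @export
write_detection_table <- function(x, path) {
  assert_feature_table(x, "detection table")
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write miRNA target-prediction tables
#'
#' TSV columns: `mirna_id`, `gene_id`, `algorithms` (semicolon-separated
#' labels of the prediction algorithms supporting the pair). In memory the
#' `algorithms` column is a list of character vectors and `n_algorithms`
#' carries its length.
#'
#' @param path File path.
#' @return A prediction tibble with columns `mirna_id`, `gene_id`,
#'   `algorithms` (list), `n_algorithms`.
#' @export
read_prediction_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("mirna_id", "gene_id", "algorithms")
  if (!all(required %in% names(x))) {
    stop_mirlag("prediction table must have columns %s", paste(required, collapse = ", "))
  }
  out <- tibble::tibble(
    mirna_id = x$mirna_id,
    gene_id = x$gene_id,
    algorithms = stringr::str_split(x$algorithms, ";")
  )
  as_prediction_table(out)
}

#' @param x A prediction tibble.
#' @rdname read_prediction_table
#' @export
write_prediction_table <- function(x, path) {
  x <- as_prediction_table(x)
  out <- tibble::tibble(
    mirna_id = x$mirna_id,
    gene_id = x$gene_id,
    algorithms = purrr::map_chr(x$algorithms, paste, collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Coerce to a valid prediction table
#'
#' Validates unique (miRNA, gene) pairs and non-empty algorithm sets, and
#' (re)computes `n_algorithms`.
#'
#' @param x A data frame with `mirna_id`, `gene_id` and a list-column
#'   `algorithms`.
#' @return A validated prediction tibble.
#' @export
as_prediction_table <- function(x) {
  if (!all(c("mirna_id", "gene_id", "algorithms") %in% names(x))) {
    stop_mirlag("need columns mirna_id, gene_id, algorithms")
  }
  if (anyDuplicated(paste(x$mirna_id, x$gene_id)) > 0) {
    stop_mirlag("duplicate (mirna_id, gene_id) pairs in prediction table")
  }
  x <- tibble::as_tibble(x)
  x$algorithms <- purrr::map(x$algorithms, unique)
  x$n_algorithms <- lengths(x$algorithms)
  if (nrow(x) > 0 && any(x$n_algorithms == 0)) {
    stop_mirlag("empty algorithm set in prediction table")
  }
  x
}

#' Read and write gene-set annotation in GMT format
#'
#' One term per line: `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`. In
#' memory the annotation is a long tibble (`term_id`, `term_name`,
#' `gene_id`).
#'
#' @param path File path.
#' @return A long annotation tibble.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  bad <- lengths(parts) < 3
  if (any(bad)) stop_mirlag("GMT line without genes: %s", parts[[which(bad)[1]]][1])
  purrr::map_dfr(parts, function(p) {
    tibble::tibble(term_id = p[1], term_name = p[2], gene_id = unique(p[-(1:2)]))
  })
}

#' @param annotation A long annotation tibble.
#' @rdname read_gmt
#' @export
write_gmt <- function(annotation, path) {
  lines <- annotation |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(genes = paste(.data$gene_id, collapse = "\t"), .groups = "drop") |>
    dplyr::mutate(line = paste(.data$term_id, .data$term_name, .data$genes, sep = "\t"))
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Read and write qPCR threshold-cycle tables
#'
#' TSV columns: `feature_id`, `sample_id` (encoded as for expression tables),
#' `tech_rep`, `ct`.
#'
#' @param path File path.
#' @return A long Ct tibble.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    sample_id = readr::col_character(),
    tech_rep = readr::col_integer(),
    ct = readr::col_double()
  ))
  if (anyNA(x$ct) || any(!is.finite(x$ct))) stop_mirlag("non-finite Ct values in %s", path)
  parse_sample_ids(unique(x$sample_id))
  x
}

#' @param x A long Ct tibble.
#' @rdname read_ct_table
#' @export
write_ct_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
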