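#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an interaction network into its edge list
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return The edge tibble, with the network name attached.
#' @export
tidy.interaction_network <- function(x, ...) {
  dplyr::mutate(x$edges, network = x$name, .before = 1)
}

#' One-row network summary
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A tibble: `network`, `n_mirnas`, `n_genes`, `n_edges`.
#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(
    network = x$name,
    n_mirnas = length(x$mirna_nodes),
    n_genes = length(x$gene_nodes),
    n_edges = nrow(x$edges)
  )
}

#' Tidy a validation summary into per-candidate rows
#'
#' @param x A `validation_summary`.
#' @param ... Unused.
#' @export
tidy.validation_summary <- function(x, ...) x$candidates

#' One-row validation summary
#'
#' @param x A `validation_summary`.
#' @param ... Unused.
#' @return A tibble with tested/confirmed counts and percentages per
#'   direction and overall.
#' @export
glance.validation_summary <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(
      names_from = "direction",
      values_from = c("tested", "confirmed", "pct_confirmed")
    )
}

#' Tidy a reference-stability selection
#'
#' @param x A `ref_selection`.
#' @param ... Unused.
#' @return The stability ranking with a `chosen` flag.
#' @export
tidy.ref_selection <- function(x, ...) {
  dplyr::mutate(x$stability, chosen = .data$feature_id %in% x$references)
}
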