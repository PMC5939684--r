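#' Keep predictions supported by at least k algorithms
#'
#' The consensus-prediction filter: only miRNA-gene pairs predicted by at
#' least `k` algorithms (default 2) are considered further.
#'
#' @param predictions A prediction tibble.
#' @param k Minimum supporting-algorithm count (>= 1).
#' @return The filtered prediction tibble.
#' @export
filter_min_algorithms <- function(predictions, k = 2) {
  if (k < 1) stop_mirlag("k must be >= 1")
  predictions <- as_prediction_table(predictions)
  dplyr::filter(predictions, .data$n_algorithms >= k)
}

#' Build a time-indexed inverse-expression miRNA-mRNA network
#'
#' An edge (miRNA m, gene g) is included iff the pair is predicted, m is in
#' the group's filtered miRNA DE set, g is in the filtered mRNA DE set at
#' the network's timepoint, g is detected in at least one mRNA array, and
#' the two fold changes have opposite signs. The result is bipartite by
#' construction; node sets are exactly the edge endpoints. The study builds
#' three such networks: group A miRNAs against DE mRNAs at P15 (`A15`) and
#' P17 (`A17`, the time-delayed network) and group B against DE mRNAs at
#' P17 (`B17`).
#'
#' @param name Network name (e.g. `"A17"`).
#' @param mirna_de Filtered miRNA DE tibble for the group (one row per
#'   miRNA; its `signed_fc` anchors the sign comparison).
#' @param mrna_de Filtered mRNA DE tibble at the network timepoint.
#' @param predictions Algorithm-filtered prediction tibble.
#' @param mrna_calls Detection tibble for the mRNA platform.
#' @return An `interaction_network`: list with `name`, `edges` tibble
#'   (`mirna_id`, `gene_id`, `mirna_signed_fc`, `mrna_signed_fc`,
#'   `algorithm_count`) and the two node sets.
#' @export
build_inverse_network <- function(name, mirna_de, mrna_de, predictions, mrna_calls) {
  predictions <- as_prediction_table(predictions)
  if (anyDuplicated(mirna_de$feature_id) > 0 || anyDuplicated(mrna_de$feature_id) > 0) {
    stop_mirlag("DE tables must have one row per feature")
  }
  detected <- mrna_calls$feature_id[
    rowSums(as.matrix(mrna_calls[, sample_cols(mrna_calls)]) == "P") >= 1
  ]
  edges <- predictions |>
    dplyr::inner_join(
      dplyr::select(mirna_de, mirna_id = "feature_id", mirna_signed_fc = "signed_fc"),
      by = "mirna_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(mrna_de, gene_id = "feature_id", mrna_signed_fc = "signed_fc"),
      by = "gene_id"
    ) |>
    dplyr::filter(
      .data$gene_id %in% detected,
      sign(.data$mirna_signed_fc) * sign(.data$mrna_signed_fc) == -1
    ) |>
    dplyr::transmute(
      mirna_id = .data$mirna_id, gene_id = .data$gene_id,
      mirna_signed_fc = .data$mirna_signed_fc,
      mrna_signed_fc = .data$mrna_signed_fc,
      algorithm_count = .data$n_algorithms
    )
  structure(
    list(name = name, edges = edges,
         mirna_nodes = unique(edges$mirna_id),
         gene_nodes = unique(edges$gene_id)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network %s> %d miRNAs, %d genes, %d edges\n",
              x$name, length(x$mirna_nodes), length(x$gene_nodes), nrow(x$edges)))
  invisible(x)
}

#' Union of gene nodes across networks
#'
#' The inversely expressed gene set: every gene appearing in any of the
#' supplied networks, deduplicated.
#'
#' @param networks A list of `interaction_network` objects (or a single
#'   one).
#' @return A character vector of unique gene ids.
#' @export
inverse_gene_set <- function(networks) {
  if (inherits(networks, "interaction_network")) networks <- list(networks)
  unique(unlist(purrr::map(networks, "gene_nodes"), use.names = FALSE))
}

#' Export a network for external viewers
#'
#' Formats: `"sif"` (lines `mirna_id targets gene_id`), `"graphml"` (node
#' attribute `node_type` in {mirna, gene}; edge attributes both fold
#' changes and the algorithm count) and `"tsv"` (full edge list). All
#' outputs are re-readable (GraphML via igraph, TSV via
#' [read_network_tsv()]).
#'
#' @param network An `interaction_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- network$edges
  if (format == "tsv") {
    readr::write_tsv(edges, path)
  } else if (format == "sif") {
    readr::write_lines(
      if (nrow(edges) > 0) paste(edges$mirna_id, "targets", edges$gene_id) else character(),
      path
    )
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an interaction network to an igraph object
#'
#' @param network An `interaction_network`.
#' @return A bipartite igraph graph with `node_type` vertex attribute.
#' @export
as_igraph <- function(network) {
  edges <- network$edges
  verts <- tibble::tibble(
    name = c(network$mirna_nodes, network$gene_nodes),
    node_type = c(rep("mirna", length(network$mirna_nodes)),
                  rep("gene", length(network$gene_nodes)))
  )
  igraph::graph_from_data_frame(
    d = edges[, c("mirna_id", "gene_id", "mirna_signed_fc", "mrna_signed_fc", "algorithm_count")],
    directed = TRUE, vertices = verts
  )
}

#' Read a TSV network edge list back into an interaction network
#'
#' @param path TSV written by [export_network()].
#' @param name Network name to attach.
#' @return An `interaction_network`.
#' @export
read_network_tsv <- function(path, name = "imported") {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), gene_id = readr::col_character(),
    .default = readr::col_double()
  ))
  structure(
    list(name = name, edges = tibble::as_tibble(edges),
         mirna_nodes = unique(edges$mirna_id),
         gene_nodes = unique(edges$gene_id)),
    class = "interaction_network"
  )
}
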