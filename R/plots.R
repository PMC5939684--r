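#' Plot fold-change trajectories of selected features
#'
#' One line per feature and reference (age-matched control vs pre-onset
#' baseline), signed fold change against timepoint, with the candidate
#' cutoff band marked.
#'
#' @param de_all Combined DE tibble (all comparisons).
#' @param features Feature ids to plot.
#' @param fc_cutoff Cutoff band to draw.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(de_all, features, fc_cutoff = 1.5) {
  dat <- purrr::map_dfr(features, ~ track_trajectory(de_all, .x))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$timepoint, y = .data$signed_fc,
                                    colour = .data$feature_id,
                                    group = interaction(.data$feature_id, .data$reference),
                                    linetype = .data$reference)) +
    ggplot2::geom_hline(yintercept = c(-fc_cutoff, fc_cutoff), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "timepoint", y = "signed fold change",
                  colour = "feature", linetype = "reference") +
    ggplot2::theme_minimal()
}

#' Plot an interaction network
#'
#' Bipartite layout with miRNAs on the left and target genes on the right;
#' edge colour encodes the regulator's direction.
#'
#' @param object An `interaction_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_network <- function(object, ...) {
  edges <- object$edges
  nodes <- tibble::tibble(
    name = c(object$mirna_nodes, object$gene_nodes),
    node_type = c(rep("mirna", length(object$mirna_nodes)),
                  rep("gene", length(object$gene_nodes)))
  ) |>
    dplyr::group_by(.data$node_type) |>
    dplyr::mutate(x = ifelse(.data$node_type == "mirna", 0, 1),
                  y = seq(0, 1, length.out = max(dplyr::n(), 2))[seq_len(dplyr::n())]) |>
    dplyr::ungroup()
  seg <- edges |>
    dplyr::left_join(dplyr::select(nodes, mirna_id = "name", x0 = "x", y0 = "y"), by = "mirna_id") |>
    dplyr::left_join(dplyr::select(nodes, gene_id = "name", x1 = "x", y1 = "y"), by = "gene_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   colour = .data$mirna_signed_fc > 0),
      alpha = 0.5
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, shape = .data$node_type),
                        size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
                                 labels = c(`TRUE` = "miRNA up", `FALSE` = "miRNA down")) +
    ggplot2::labs(title = object$name, colour = "regulator", shape = "node") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot enrichment results
#'
#' Horizontal bars of -log10 adjusted P for the top terms.
#'
#' @param enrichment Tibble from [enrich()].
#' @param top Number of terms to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 15) {
  dat <- utils::head(enrichment, top)
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(.data$p_adj),
                                    y = stats::reorder(.data$term_name, -.data$p_adj),
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 adjusted P", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}
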