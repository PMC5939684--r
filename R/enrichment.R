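#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when sampling `n` genes without replacement
#' from a universe of `N` genes of which `K` carry the annotation. Computed
#' in log space via the stable distribution-function routine; vectorized.
#'
#' @param k Observed hits.
#' @param K Annotated genes in the universe (term size).
#' @param n Sample (gene-set) size.
#' @param N Universe size.
#' @return Upper-tail probabilities.
#' @examples
#' hypergeometric_upper(5, 5, 5, 10) # 1/252
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  k <- args[, 1]; K <- args[, 2]; n <- args[, 3]; N <- args[, 4]
  if (any(K < 0 | K > N | n < 0 | n > N | k < 0 | k > pmin(K, n))) {
    stop_mirlag("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  }
  unname(exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)))
}

#' Over-representation analysis of a gene set
#'
#' Tests each annotation term for over-representation in `gene_set`
#' relative to `universe` with the hypergeometric upper tail, adjusting by
#' Benjamini-Hochberg across tested terms. Term gene sets are intersected
#' with the universe first; terms smaller than `min_term_size` after
#' intersection are skipped. The recommended universe is the set of
#' detected (retina-expressed) genes, not the whole annotation, to avoid
#' expression-bias inflation.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector: the background gene population.
#' @param annotation Long annotation tibble (`term_id`, `term_name`,
#'   `gene_id`), e.g. from [read_gmt()].
#' @param min_term_size Minimum effective term size.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble sorted by `p_adj` with columns `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant`.
#' @export
enrich <- function(gene_set, universe, annotation, min_term_size = 3, alpha = 0.05) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    stop_mirlag("gene_set must be a subset of the universe")
  }
  ann <- dplyr::filter(annotation, .data$gene_id %in% universe)
  terms <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% gene_set),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K >= min_term_size)
  if (nrow(terms) == 0) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          k = integer(), K = integer(), n = integer(), N = integer(),
                          p_raw = numeric(), p_adj = numeric(), significant = logical()))
  }
  terms |>
    dplyr::mutate(
      n = length(gene_set), N = length(universe),
      p_raw = hypergeometric_upper(.data$k, .data$K, .data$n, .data$N),
      p_adj = stats::p.adjust(.data$p_raw, method = "BH"),
      significant = .data$p_adj < alpha
    ) |>
    dplyr::arrange(.data$p_adj, .data$p_raw)
}
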