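# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# exhaustive hypergeometric upper tail via binomial coefficients
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force inverse-network edge set: loop over the full cross product
oracle_network_edges <- function(mirna_de, mrna_de, predictions, detected_genes) {
  out <- list()
  for (i in seq_len(nrow(predictions))) {
    m <- predictions$mirna_id[i]; g <- predictions$gene_id[i]
    im <- match(m, mirna_de$feature_id); ig <- match(g, mrna_de$feature_id)
    if (is.na(im) || is.na(ig)) next
    if (!(g %in% detected_genes)) next
    fm <- mirna_de$signed_fc[im]; fg <- mrna_de$signed_fc[ig]
    if (sign(fm) * sign(fg) != -1) next
    out[[length(out) + 1]] <- c(m, g)
  }
  if (length(out) == 0) return(character())
  sort(vapply(out, paste, "", collapse = "|"))
}

# a compact simulated dataset reused by several tests
small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(n_mirna = 60, n_mrna = 150, frac_groupA = 0.1, frac_groupB = 0.1,
                    targets_per_mirna = 2, frac_background = 0.2,
                    false_prediction_rate = 0.005, seed = seed, ...)
  list(cfg = cfg, sim = simulate_expression(cfg))
}

# validation-panel simulation used by the classification benchmarks:
# 25 candidate-scale features, 7 pre-onset (A), 8 post-onset (B), 10 null
panel_sim <- function(seed) {
  sim_config(n_mirna = 25, n_mrna = 50, frac_groupA = 7 / 25, frac_groupB = 8 / 25,
             effect_log2 = 1.5, noise_sd = 0.25, n_replicates = 3,
             targets_per_mirna = 1, frac_background = 0, seed = seed)
}

classify_panel <- function(seed, rule = "disjunctive") {
  cfg <- panel_sim(seed)
  sim <- simulate_expression(cfg)
  de <- purrr::map_dfr(rd10_comparisons(), ~ differential_expression(sim$mirna_expr, .x))
  prof <- temporal_profiles(de, fc_cutoff = 1.5, alpha = 0.05)
  grp <- suppressWarnings(classify_groups(prof, rule = rule))
  dplyr::inner_join(grp, sim$truth$de_mirnas, by = "feature_id",
                    suffix = c("_called", "_true"))
}
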