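#' Simulation configuration for the rd10-style study design
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design that motivates the package: two
#' genotypes (rd10, WT) at three postnatal timepoints (P13, P15, P17) with
#' triplicate pooled retinal samples, ~1900 miRNA features, a larger mRNA
#' panel, a subset of miRNAs with a pre-onset (group A) or post-onset-only
#' (group B) planted differential-expression signature, and delayed inverse
#' responses among their predicted target mRNAs. Photoreceptor apoptosis in
#' rd10 begins around P16, so "pre-onset" means P13/P15 and "post-onset"
#' means P17.
#'
#' Signals are simulated on the log2 scale (additive noise) and exported on
#' the linear scale, the convention of array analysis.
#'
#' @param n_mirna,n_mrna Feature counts for the two platforms.
#' @param genotypes Two genotype labels, case first.
#' @param timepoints Ordered timepoint labels.
#' @param n_replicates Biological replicates per genotype x timepoint group.
#' @param frac_groupA,frac_groupB Fractions of miRNAs carrying the pre-onset
#'   (A) and post-onset-only (B) signatures; must sum to at most 1.
#' @param effect_log2 Planted |log2 ratio| for DE miRNAs.
#' @param mrna_effect_log2 Planted |log2 ratio| for responding target mRNAs.
#' @param p13_effect_log2 Optional smaller group-A effect already present at
#'   P13 (0 disables it; the default). Group A always has the full effect at
#'   P15 and P17.
#' @param noise_sd Log2-scale replicate noise SD.
#' @param background_mu,background_sd Log2 background-signal model; the
#'   detection threshold is its 0.95 quantile.
#' @param frac_background Fraction of features sitting at background level
#'   (flagged absent in ~95% of arrays).
#' @param p_up Probability that a planted DE feature is upregulated.
#' @param targets_per_mirna True target genes per DE miRNA.
#' @param false_prediction_rate Per-pair probability of a spurious
#'   prediction edge.
#' @param spurious_single_algo_frac Fraction of spurious prediction rows
#'   supported by a single algorithm (true pairs always have >= 2).
#' @param groupA_targets_at_p15 If `TRUE`, group-A targets also respond at
#'   P15; by default they respond only at P17 (the time-delayed pattern).
#' @param algo_names At least four prediction-algorithm labels.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_mirna = 1900,
                       n_mrna = 5000,
                       genotypes = c("rd10", "WT"),
                       timepoints = c("P13", "P15", "P17"),
                       n_replicates = 3,
                       frac_groupA = 0.02,
                       frac_groupB = 0.04,
                       effect_log2 = 1.5,
                       mrna_effect_log2 = 0.6,
                       p13_effect_log2 = 0,
                       noise_sd = 0.25,
                       background_mu = 4,
                       background_sd = 0.5,
                       frac_background = 0.2,
                       p_up = 0.5,
                       targets_per_mirna = 5,
                       false_prediction_rate = 0.001,
                       spurious_single_algo_frac = 0.6,
                       groupA_targets_at_p15 = FALSE,
                       algo_names = c("miRWalk", "miRanda", "TargetScan", "RNA22"),
                       seed = 1L) {
  cfg <- list(
    n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
    genotypes = genotypes, timepoints = timepoints,
    n_replicates = as.integer(n_replicates),
    frac_groupA = frac_groupA, frac_groupB = frac_groupB,
    effect_log2 = effect_log2, mrna_effect_log2 = mrna_effect_log2,
    p13_effect_log2 = p13_effect_log2,
    noise_sd = noise_sd,
    background_mu = background_mu, background_sd = background_sd,
    frac_background = frac_background, p_up = p_up,
    targets_per_mirna = as.integer(targets_per_mirna),
    false_prediction_rate = false_prediction_rate,
    spurious_single_algo_frac = spurious_single_algo_frac,
    groupA_targets_at_p15 = isTRUE(groupA_targets_at_p15),
    algo_names = algo_names,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_mirna, cfg$n_mrna, cfg$n_replicates, cfg$targets_per_mirna)
  if (any(counts <= 0)) stop_mirlag("all counts must be > 0")
  if (cfg$frac_groupA < 0 || cfg$frac_groupB < 0 || cfg$frac_groupA + cfg$frac_groupB > 1) {
    stop_mirlag("frac_groupA + frac_groupB must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) stop_mirlag("noise_sd must be >= 0")
  if (length(cfg$genotypes) != 2) stop_mirlag("exactly two genotypes required")
  if (anyDuplicated(cfg$timepoints) > 0 || length(cfg$timepoints) < 2) {
    stop_mirlag("timepoints must be distinct ordered labels")
  }
  if (cfg$false_prediction_rate < 0 || cfg$false_prediction_rate > 1) {
    stop_mirlag("false_prediction_rate must be in [0, 1]")
  }
  if (length(cfg$algo_names) < 4) stop_mirlag("need >= 4 algorithm labels")
  invisible(cfg)
}

sim_sample_ids <- function(cfg) {
  grid <- expand.grid(
    replicate = seq_len(cfg$n_replicates),
    timepoint = cfg$timepoints,
    genotype = cfg$genotypes,
    stringsAsFactors = FALSE
  )
  paste(grid$genotype, grid$timepoint, grid$replicate, sep = "_")
}

detection_threshold <- function(cfg) {
  stats::qnorm(0.95, cfg$background_mu, cfg$background_sd)
}

# planted log2 shift for feature f in (genotype, timepoint); truth rows carry
# per-timepoint ratios so this is a lookup against the case genotype
planted_shift_matrix <- function(ids, shifts_by_tp, meta, case_genotype) {
  out <- matrix(0, nrow = length(ids), ncol = nrow(meta), dimnames = list(ids, meta$sample_id))
  for (tp in colnames(shifts_by_tp)) {
    cols <- meta$genotype == case_genotype & meta$timepoint == tp
    if (any(cols)) out[, cols] <- shifts_by_tp[, tp]
  }
  out
}

#' Simulate miRNA and mRNA expression with planted ground truth
#'
#' Draws per-feature baseline log2 levels, plants the group-A (effect at P15
#' and P17, optionally a smaller one at P13) and group-B (effect at P17
#' only) miRNA signatures in the case genotype, assigns each DE miRNA a set
#' of true target genes that shift in the opposite direction (group-A
#' targets with a delayed response at P17), adds i.i.d. log2 replicate
#' noise, and derives present/absent detection calls against the background
#' 0.95 quantile. A `frac_background` fraction of features carries pure
#' background signal.
#'
#' @param config A [sim_config()].
#' @return A list with elements `mirna_expr`, `mrna_expr` (wide linear-scale
#'   expression tibbles), `mirna_calls`, `mrna_calls` (detection tibbles)
#'   and `truth`, a `ground_truth` list with tibbles `de_mirnas`
#'   (feature_id, group, direction, per-timepoint true log2 ratios),
#'   `true_targets` (mirna_id, gene_id, response_timepoint, gene_lfc) and
#'   internal per-feature baseline means used by [simulate_qpcr()].
#' @export
simulate_expression <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed)

  ids_mi <- sprintf("miR-%04d", seq_len(cfg$n_mirna))
  ids_g <- sprintf("gene-%05d", seq_len(cfg$n_mrna))
  sample_ids <- sim_sample_ids(cfg)
  meta <- parse_sample_ids(sample_ids)
  thr <- detection_threshold(cfg)
  case <- cfg$genotypes[1]
  tps <- cfg$timepoints

  n_A <- round(cfg$frac_groupA * cfg$n_mirna)
  n_B <- round(cfg$frac_groupB * cfg$n_mirna)
  n_bg_mi <- round(cfg$frac_background * cfg$n_mirna)
  n_bg_g <- round(cfg$frac_background * cfg$n_mrna)

  # feature roles: DE miRNAs first, then background, then expressed nulls
  de_ids <- ids_mi[seq_len(n_A + n_B)]
  groupA_ids <- de_ids[seq_len(n_A)]
  groupB_ids <- setdiff(de_ids, groupA_ids)
  bg_mi <- ids_mi[n_A + n_B + seq_len(min(n_bg_mi, cfg$n_mirna - n_A - n_B))]

  direction <- ifelse(stats::runif(n_A + n_B) < cfg$p_up, 1, -1)

  shifts <- matrix(0, nrow = n_A + n_B, ncol = length(tps),
                   dimnames = list(de_ids, tps))
  if (n_A + n_B > 0) {
    p15 <- tps[2]; p17 <- tps[3]; p13 <- tps[1]
    if (n_A > 0) {
      shifts[groupA_ids, p15] <- direction[seq_len(n_A)] * cfg$effect_log2
      shifts[groupA_ids, p17] <- direction[seq_len(n_A)] * cfg$effect_log2
      if (cfg$p13_effect_log2 > 0) {
        shifts[groupA_ids, p13] <- direction[seq_len(n_A)] * cfg$p13_effect_log2
      }
    }
    if (n_B > 0) {
      shifts[groupB_ids, p17] <- direction[n_A + seq_len(n_B)] * cfg$effect_log2
    }
  }

  # baseline log2 means: expressed features well above background
  base_mi <- stats::runif(cfg$n_mirna, cfg$background_mu + 3, cfg$background_mu + 8)
  names(base_mi) <- ids_mi
  base_g <- stats::runif(cfg$n_mrna, cfg$background_mu + 3, cfg$background_mu + 8)
  names(base_g) <- ids_g

  # true targets: disjoint gene sets per DE miRNA, drawn from expressed genes
  n_targets <- (n_A + n_B) * cfg$targets_per_mirna
  expressed_g <- ids_g[seq_len(cfg$n_mrna - n_bg_g)]
  bg_g <- setdiff(ids_g, expressed_g)
  if (n_targets > length(expressed_g)) {
    stop_mirlag("not enough expressed genes for %d true targets", n_targets)
  }
  if (n_targets > 0) {
    target_genes <- sample(expressed_g, n_targets)
    true_targets <- tibble::tibble(
      mirna_id = rep(de_ids, each = cfg$targets_per_mirna),
      gene_id = target_genes
    ) |>
      dplyr::mutate(
        mirna_direction = rep(direction, each = cfg$targets_per_mirna),
        response_timepoint = tps[3],
        gene_lfc = -.data$mirna_direction * cfg$mrna_effect_log2
      )
  } else {
    true_targets <- tibble::tibble(
      mirna_id = character(), gene_id = character(),
      mirna_direction = numeric(), response_timepoint = character(),
      gene_lfc = numeric()
    )
  }

  gene_shifts <- matrix(0, nrow = nrow(true_targets), ncol = length(tps),
                        dimnames = list(true_targets$gene_id, tps))
  if (nrow(true_targets) > 0) {
    gene_shifts[, tps[3]] <- true_targets$gene_lfc
    if (cfg$groupA_targets_at_p15) {
      is_A_target <- true_targets$mirna_id %in% groupA_ids
      gene_shifts[is_A_target, tps[2]] <- true_targets$gene_lfc[is_A_target]
    }
  }

  build_matrix <- function(ids, base, bg_ids, shift_rows) {
    mu <- matrix(rep(base, length(sample_ids)), nrow = length(ids),
                 dimnames = list(ids, sample_ids))
    if (nrow(shift_rows) > 0) {
      shift_full <- planted_shift_matrix(rownames(shift_rows), shift_rows, meta, case)
      mu[rownames(shift_rows), ] <- mu[rownames(shift_rows), , drop = FALSE] + shift_full
    }
    log2sig <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd), nrow = nrow(mu))
    # background features: pure background draws, no feature-level mean
    if (length(bg_ids) > 0) {
      log2sig[bg_ids, ] <- matrix(
        stats::rnorm(length(bg_ids) * length(sample_ids), cfg$background_mu, cfg$background_sd),
        nrow = length(bg_ids)
      )
    }
    log2sig
  }

  log2_mi <- build_matrix(ids_mi, base_mi, bg_mi, shifts)
  log2_g <- build_matrix(ids_g, base_g, bg_g, gene_shifts)

  calls_from <- function(log2sig) {
    m <- ifelse(log2sig > thr, "P", "A")
    matrix_to_tbl(m)
  }

  de_mirnas <- tibble::tibble(
    feature_id = de_ids,
    group = c(rep("A", n_A), rep("B", n_B)),
    direction = direction
  )
  if (nrow(de_mirnas) > 0) {
    for (tp in tps) de_mirnas[[paste0("lfc_", tp)]] <- unname(shifts[, tp])
  } else {
    for (tp in tps) de_mirnas[[paste0("lfc_", tp)]] <- numeric()
  }

  truth <- structure(list(
    de_mirnas = de_mirnas,
    true_targets = true_targets[, c("mirna_id", "gene_id", "response_timepoint", "gene_lfc")],
    background_features = c(bg_mi, bg_g),
    base_log2 = c(base_mi, base_g),
    shift_log2 = rbind(shifts, gene_shifts),
    config = cfg
  ), class = "ground_truth")

  list(
    mirna_expr = matrix_to_tbl(2^log2_mi),
    mrna_expr = matrix_to_tbl(2^log2_g),
    mirna_calls = calls_from(log2_mi),
    mrna_calls = calls_from(log2_g),
    truth = truth
  )
}

#' Simulate a target-prediction table consistent with the ground truth
#'
#' Every planted true (miRNA, gene) regulation appears with at least two
#' supporting algorithms, mimicking a consensus-prediction export. Spurious
#' pairs are added at `false_prediction_rate` over the remaining miRNA x
#' gene grid with an algorithm-support distribution skewed toward
#' single-algorithm calls.
#'
#' @param config A [sim_config()].
#' @param truth The `ground_truth` from [simulate_expression()] for the same
#'   config.
#' @return A prediction tibble (see [read_prediction_table()]).
#' @export
simulate_prediction_table <- function(config, truth) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  if (!inherits(truth, "ground_truth")) stop_mirlag("truth must come from simulate_expression()")
  if (!identical(truth$config$seed, cfg$seed) ||
      !identical(truth$config$n_mirna, cfg$n_mirna) ||
      !identical(truth$config$n_mrna, cfg$n_mrna)) {
    stop_mirlag("truth was generated from a different config")
  }
  set.seed(cfg$seed + 1L)

  ids_mi <- sprintf("miR-%04d", seq_len(cfg$n_mirna))
  ids_g <- sprintf("gene-%05d", seq_len(cfg$n_mrna))
  tt <- truth$true_targets
  algo <- cfg$algo_names

  draw_support <- function(n, probs) {
    k <- sample(seq_along(probs), n, replace = TRUE, prob = probs)
    purrr::map(k, ~ sample(algo, .x))
  }

  true_rows <- tibble::tibble(
    mirna_id = tt$mirna_id,
    gene_id = tt$gene_id,
    algorithms = draw_support(nrow(tt), c(0, 0.4, 0.3, 0.3))
  )

  n_pairs_total <- as.double(cfg$n_mirna) * cfg$n_mrna
  true_idx <- (match(tt$mirna_id, ids_mi) - 1) * cfg$n_mrna + match(tt$gene_id, ids_g)
  n_free <- n_pairs_total - nrow(tt)
  n_spurious <- stats::rbinom(1, n_free, cfg$false_prediction_rate)

  if (n_spurious > 0) {
    if (n_pairs_total <= 2e6) {
      free_idx <- setdiff(seq_len(n_pairs_total), true_idx)
      idx <- sample(free_idx, n_spurious)
    } else {
      idx <- sample(n_pairs_total, min(n_spurious * 1.2 + 10, n_pairs_total))
      idx <- setdiff(idx, true_idx)[seq_len(min(n_spurious, length(idx)))]
    }
    f <- cfg$spurious_single_algo_frac
    probs <- c(f, (1 - f) * c(0.625, 0.25, 0.125))
    spurious_rows <- tibble::tibble(
      mirna_id = ids_mi[(idx - 1) %/% cfg$n_mrna + 1],
      gene_id = ids_g[(idx - 1) %% cfg$n_mrna + 1],
      algorithms = draw_support(length(idx), probs)
    )
  } else {
    spurious_rows <- true_rows[0, ]
  }

  as_prediction_table(dplyr::bind_rows(true_rows, spurious_rows))
}

#' Simulate annotation gene sets with planted enriched terms
#'
#' Builds a GMT-style annotation: `n_planted` terms drawn mostly from the
#' responding target genes (so they are truly over-represented among
#' inversely expressed genes) plus `n_random` terms sampled uniformly from
#' all genes.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @param n_planted,n_random Term counts.
#' @param term_size Genes per term.
#' @param planted_purity Fraction of a planted term's genes drawn from the
#'   responding target genes.
#' @return A long annotation tibble; planted term ids start with
#'   `"planted_"`.
#' @export
simulate_annotation <- function(config, truth, n_planted = 5, n_random = 45,
                                term_size = 20, planted_purity = 0.7) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed + 2L)
  ids_g <- sprintf("gene-%05d", seq_len(cfg$n_mrna))
  responders <- unique(truth$true_targets$gene_id)

  one_term <- function(id, name, pool_hit, purity) {
    n_hit <- min(round(purity * term_size), length(pool_hit))
    genes <- c(sample(pool_hit, n_hit),
               sample(setdiff(ids_g, pool_hit), term_size - n_hit))
    tibble::tibble(term_id = id, term_name = name, gene_id = unique(genes))
  }

  planted <- purrr::map_dfr(seq_len(if (length(responders) >= 2) n_planted else 0), function(i) {
    one_term(sprintf("planted_%02d", i), sprintf("planted term %d", i), responders, planted_purity)
  })
  random <- purrr::map_dfr(seq_len(n_random), function(i) {
    tibble::tibble(term_id = sprintf("random_%03d", i),
                   term_name = sprintf("random term %d", i),
                   gene_id = sample(ids_g, term_size))
  })
  dplyr::bind_rows(planted, random)
}

#' Simulate qPCR threshold-cycle tables
#'
#' Models Ct as `intercept - log2(true expression) + N(0, ct_noise_sd)` per
#' technical replicate, with triplicate technical replicates per biological
#' sample. Designated reference features have genotype- and
#' timepoint-invariant true expression, mimicking stable endogenous
#' controls.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @param features Feature ids (miRNA or gene) from the truth's id space.
#' @param references Ids of simulated stable reference assays (created here;
#'   they need not exist on the arrays).
#' @param intercept Ct intercept (cycles at unit expression).
#' @param ct_noise_sd Technical noise SD in cycles; defaults to the
#'   config's `noise_sd`.
#' @param n_tech_rep Technical replicates per biological sample.
#' @return A long Ct tibble (`feature_id`, `sample_id`, `tech_rep`, `ct`).
#' @export
simulate_qpcr <- function(config, truth, features,
                          references = c("ref-1", "ref-2", "ref-3"),
                          intercept = 35, ct_noise_sd = NULL, n_tech_rep = 3) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  if (is.null(ct_noise_sd)) ct_noise_sd <- cfg$noise_sd
  unknown <- setdiff(features, names(truth$base_log2))
  if (length(unknown) > 0) {
    stop_mirlag("unknown feature id(s): %s", paste(unknown[1:min(3, length(unknown))], collapse = ", "))
  }
  set.seed(cfg$seed + 3L)

  sample_ids <- sim_sample_ids(cfg)
  meta <- parse_sample_ids(sample_ids)
  case <- cfg$genotypes[1]

  ref_base <- stats::setNames(6 + seq_along(references), references)
  all_feats <- c(features, references)

  grid <- tidyr::expand_grid(
    feature_id = all_feats,
    sample_id = sample_ids,
    tech_rep = seq_len(n_tech_rep)
  ) |>
    dplyr::left_join(meta, by = "sample_id")

  shift_for <- function(fid, genotype, timepoint) {
    if (!fid %in% rownames(truth$shift_log2)) return(rep(0, length(genotype)))
    ifelse(genotype == case, truth$shift_log2[fid, timepoint], 0)
  }
  grid$log2_expr <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    fid <- grid$feature_id[i]
    base <- if (fid %in% references) ref_base[[fid]] else truth$base_log2[[fid]]
    base + shift_for(fid, grid$genotype[i], grid$timepoint[i])
  })
  grid$ct <- intercept - grid$log2_expr +
    stats::rnorm(nrow(grid), 0, ct_noise_sd)
  grid[, c("feature_id", "sample_id", "tech_rep", "ct")]
}
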