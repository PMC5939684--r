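#' Pipeline configuration
#'
#' Collects the study thresholds and either simulation settings or input
#' file paths. Thresholds default to the study's: miRNA fold-change cutoff
#' 1.5, mRNA cutoff 1.3, adjusted P < 0.05, >= 2 prediction algorithms.
#'
#' @param sim A [sim_config()] or argument list for one; used when `paths`
#'   is `NULL`.
#' @param paths Optional named list of input files (`mirna_expr`,
#'   `mirna_calls`, `mrna_expr`, `mrna_calls`, `predictions`, and
#'   optionally `annotation` (GMT), `ct` (Ct table)); switches the
#'   pipeline to file mode.
#' @param mirna_fc,mrna_fc Signed-fold-change cutoffs.
#' @param alpha Adjusted-significance level.
#' @param min_algorithms Consensus-prediction threshold.
#' @param background_margin,cv_max Quality-exclusion thresholds.
#' @param min_term_size Enrichment minimum term size.
#' @param group_a_rule `"disjunctive"` or `"conjunctive"` (see
#'   [classify_groups()]).
#' @param seed Integer seed (overrides the sim config's seed).
#' @param outdir Optional output directory; when set, every intermediate
#'   table and network is written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            mirna_fc = 1.5, mrna_fc = 1.3, alpha = 0.05,
                            min_algorithms = 2, background_margin = 1.2,
                            cv_max = 0.5, min_term_size = 3,
                            group_a_rule = c("disjunctive", "conjunctive"),
                            seed = NULL, outdir = NULL) {
  group_a_rule <- match.arg(group_a_rule)
  if (mirna_fc < 1 || mrna_fc < 1) stop_mirlag("fold-change cutoffs must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_mirlag("alpha must be in (0, 1)")
  if (min_algorithms < 1) stop_mirlag("min_algorithms must be >= 1")
  if (is.null(paths)) {
    if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
    if (!is.null(seed)) {
      sim_args <- unclass(sim); sim_args$seed <- as.integer(seed)
      sim <- do.call(sim_config, sim_args)
    }
  } else {
    required <- c("mirna_expr", "mirna_calls", "mrna_expr", "mrna_calls", "predictions")
    miss <- setdiff(required, names(paths))
    if (length(miss) > 0) stop_mirlag("paths is missing: %s", paste(miss, collapse = ", "))
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent) > 0) stop_mirlag("input file(s) not found: %s", paste(absent, collapse = ", "))
  }
  structure(list(
    sim = if (is.null(paths)) sim else NULL, paths = paths,
    mirna_fc = mirna_fc, mrna_fc = mrna_fc, alpha = alpha,
    min_algorithms = min_algorithms, background_margin = background_margin,
    cv_max = cv_max, min_term_size = min_term_size,
    group_a_rule = group_a_rule,
    seed = if (!is.null(seed)) as.integer(seed) else if (is.null(paths)) sim$seed else NA_integer_,
    outdir = outdir
  ), class = "pipeline_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_mirlag("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full integration pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> differential expression
#' -> temporal grouping -> inverse-expression networks -> enrichment ->
#' qPCR validation from one configuration, returning a run report with
#' stage-by-stage feature counts. Deterministic under the configured seed
#' in simulation mode.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `mirlag_report` list: `counts` (stage-by-stage), `de_mirna`
#'   (all comparisons), `de_mrna`, `profiles`, `groups`, `networks` (A15,
#'   A17, B17), `inverse_genes`, `enrichment`, `ref_selection`,
#'   `validation`, `truth` (simulation mode only) and a config/seed
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  if (!inherits(config, "pipeline_config")) stop_mirlag("config must be a pipeline_config()")
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  sim_mode <- is.null(config$paths)

  say("[input] %s", if (sim_mode) "simulating" else "reading files")
  if (sim_mode) {
    sim <- pipeline_stage("simulate", simulate_expression(config$sim))
    predictions <- pipeline_stage("simulate", simulate_prediction_table(config$sim, sim$truth))
    annotation <- pipeline_stage("simulate", simulate_annotation(config$sim, sim$truth))
    truth <- sim$truth
  } else {
    sim <- pipeline_stage("read", list(
      mirna_expr = read_expression_table(config$paths$mirna_expr),
      mirna_calls = read_detection_table(config$paths$mirna_calls),
      mrna_expr = read_expression_table(config$paths$mrna_expr),
      mrna_calls = read_detection_table(config$paths$mrna_calls)
    ))
    predictions <- pipeline_stage("read", read_prediction_table(config$paths$predictions))
    annotation <- if (!is.null(config$paths$annotation)) {
      pipeline_stage("read", read_gmt(config$paths$annotation))
    }
    truth <- NULL
  }

  say("[preprocess] detection filter + quantile normalization")
  pp <- pipeline_stage("preprocess", {
    mi <- quantile_normalize(filter_undetected(sim$mirna_expr, sim$mirna_calls))
    g <- quantile_normalize(filter_undetected(sim$mrna_expr, sim$mrna_calls))
    list(mirna = mi, mrna = g,
         mirna_calls = align_calls(sim$mirna_calls, mi),
         mrna_calls = align_calls(sim$mrna_calls, g))
  })

  say("[de] %d miRNA comparisons", 5)
  meta <- sample_metadata(pp$mirna)
  genotypes <- unique(meta$genotype)
  case <- if ("rd10" %in% genotypes) "rd10" else genotypes[1]
  ctrl <- setdiff(genotypes, case)[1]
  tps <- sort(unique(meta$timepoint))
  cmps <- rd10_comparisons(c(case, ctrl), tps)
  de_mi_all <- pipeline_stage("de", purrr::map_dfr(cmps, ~ differential_expression(pp$mirna, .x)))

  say("[quality] background/CV exclusions")
  qpass <- pipeline_stage("quality", {
    per_cmp <- split(de_mi_all, de_mi_all$comparison)
    pass_sets <- purrr::map(per_cmp, function(d) {
      apply_quality_exclusions(d, pp$mirna, pp$mirna_calls,
                               config$background_margin, config$cv_max)$feature_id
    })
    Reduce(intersect, pass_sets)
  })
  de_mi_q <- dplyr::filter(de_mi_all, .data$feature_id %in% qpass)

  say("[classify] temporal grouping")
  profiles <- pipeline_stage("classify",
    temporal_profiles(de_mi_q, fc_cutoff = config$mirna_fc, alpha = config$alpha,
                      control_genotype = ctrl))
  groups <- pipeline_stage("classify", classify_groups(profiles, rule = config$group_a_rule,
                                                       timepoints = tps))
  ids_A <- groups$feature_id[groups$group == "A"]
  ids_B <- groups$feature_id[groups$group == "B"]

  say("[network] A15 / A17 / B17")
  de_g_15 <- pipeline_stage("de", differential_expression(pp$mrna, cmps[[2]]))
  de_g_17 <- pipeline_stage("de", differential_expression(pp$mrna, cmps[[3]]))
  de_g_15f <- apply_de_filters(de_g_15, config$mrna_fc, config$alpha)
  de_g_17f <- apply_de_filters(de_g_17, config$mrna_fc, config$alpha)
  pred_f <- filter_min_algorithms(predictions, config$min_algorithms)
  anchor <- function(ids, tp_label) {
    dplyr::filter(de_mi_all, .data$comparison == tp_label, .data$feature_id %in% ids)
  }
  lab_wt <- function(tp) sprintf("%s_vs_%s_%s", case, ctrl, tp)
  networks <- pipeline_stage("network", list(
    A15 = build_inverse_network("A15", anchor(ids_A, lab_wt(tps[2])), de_g_15f, pred_f, pp$mrna_calls),
    A17 = build_inverse_network("A17", anchor(ids_A, lab_wt(tps[2])), de_g_17f, pred_f, pp$mrna_calls),
    B17 = build_inverse_network("B17", anchor(ids_B, lab_wt(tps[3])), de_g_17f, pred_f, pp$mrna_calls)
  ))
  inverse_genes <- inverse_gene_set(networks)

  say("[enrich] %d inversely expressed genes", length(inverse_genes))
  enrichment <- if (!is.null(annotation)) {
    pipeline_stage("enrich",
      enrich(inverse_genes, universe = pp$mrna$feature_id, annotation = annotation,
             min_term_size = config$min_term_size, alpha = config$alpha))
  }

  say("[qpcr] validation")
  candidates <- c(ids_A, ids_B)
  validation <- NULL; ref_selection <- NULL
  ct <- if (sim_mode && length(candidates) > 0) {
    pipeline_stage("qpcr", simulate_qpcr(config$sim, truth, candidates))
  } else if (!sim_mode && !is.null(config$paths$ct)) {
    pipeline_stage("qpcr", read_ct_table(config$paths$ct))
  }
  if (!is.null(ct)) {
    ref_ids <- intersect(unique(ct$feature_id), c("ref-1", "ref-2", "ref-3"))
    if (length(ref_ids) >= 2) {
      ref_selection <- pipeline_stage("qpcr", select_references(ct, ref_ids))
      smeta <- parse_sample_ids(unique(ct$sample_id))
      tp_of <- stats::setNames(c(tps[2], tps[3]),
                               c("A", "B"))
      qpcr_fcs <- purrr::map_dfr(candidates, function(fid) {
        grp <- if (fid %in% ids_A) "A" else "B"
        tp <- tp_of[[grp]]
        ddct_fold_change(
          ct, fid, ref_selection$references,
          case_samples = smeta$sample_id[smeta$genotype == case & smeta$timepoint == tp],
          control_samples = smeta$sample_id[smeta$genotype == ctrl & smeta$timepoint == tp]
        )
      })
      array_fc <- dplyr::bind_rows(
        anchor(ids_A, lab_wt(tps[2])),
        anchor(ids_B, lab_wt(tps[3]))
      )
      if (nrow(qpcr_fcs) > 0 && nrow(array_fc) > 0) {
        validation <- pipeline_stage("qpcr",
          validate_candidates(array_fc[, c("feature_id", "signed_fc")], qpcr_fcs,
                              alpha = config$alpha))
      }
    }
  }

  de_any <- unique(apply_de_filters(de_mi_all, config$mirna_fc, config$alpha)$feature_id)
  counts <- tibble::tibble(
    stage = c("raw", "detected", "de_filtered", "quality_passed", "grouped"),
    n_mirna = c(nrow(sim$mirna_expr), nrow(pp$mirna), length(de_any),
                length(intersect(de_any, qpass)),
                length(intersect(de_any, c(ids_A, ids_B))))
  )

  report <- structure(list(
    counts = counts,
    de_mirna = de_mi_all,
    de_mrna = list(P15 = de_g_15, P17 = de_g_17),
    de_mrna_filtered = list(P15 = de_g_15f, P17 = de_g_17f),
    profiles = profiles,
    groups = groups,
    networks = networks,
    inverse_genes = inverse_genes,
    enrichment = enrichment,
    ref_selection = ref_selection,
    validation = validation,
    truth = truth,
    manifest = list(seed = config$seed, config = config,
                    package_version = as.character(utils::packageVersion("mirlag")))
  ), class = "mirlag_report")

  if (!is.null(config$outdir)) write_report_files(report, pp, predictions, config$outdir)
  report
}

#' @export
print.mirlag_report <- function(x, ...) {
  cat("<mirlag_report> seed", x$manifest$seed, "\n")
  print(x$counts)
  cat("groups: A =", sum(x$groups$group == "A"), " B =", sum(x$groups$group == "B"), "\n")
  for (nw in x$networks) print(nw)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

write_report_files <- function(report, pp, predictions, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_expression_table(pp$mirna, p("mirna_normalized.tsv"))
  write_expression_table(pp$mrna, p("mrna_normalized.tsv"))
  write_detection_table(pp$mirna_calls, p("mirna_calls.tsv"))
  write_detection_table(pp$mrna_calls, p("mrna_calls.tsv"))
  readr::write_tsv(report$de_mirna, p("de_mirna.tsv"))
  readr::write_tsv(report$de_mrna$P15, p("de_mrna_P15.tsv"))
  readr::write_tsv(report$de_mrna$P17, p("de_mrna_P17.tsv"))
  readr::write_tsv(report$groups, p("groups.tsv"))
  write_prediction_table(predictions, p("predictions.tsv"))
  for (nm in names(report$networks)) {
    export_network(report$networks[[nm]], p(sprintf("network_%s.tsv", nm)), "tsv")
    export_network(report$networks[[nm]], p(sprintf("network_%s.sif", nm)), "sif")
    export_network(report$networks[[nm]], p(sprintf("network_%s.graphml", nm)), "graphml")
  }
  if (!is.null(report$enrichment)) readr::write_tsv(report$enrichment, p("enrichment.tsv"))
  if (!is.null(report$validation)) {
    readr::write_tsv(report$validation$candidates, p("validation_candidates.tsv"))
    readr::write_tsv(report$validation$summary, p("validation_summary.tsv"))
  }
  readr::write_lines(c(
    sprintf("seed: %s", report$manifest$seed),
    sprintf("package_version: %s", report$manifest$package_version),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), p("manifest.txt"))
  readr::write_tsv(report$counts, p("stage_counts.tsv"))
  invisible(outdir)
}
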