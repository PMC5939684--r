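#' Per-miRNA significance pattern across the comparison set
#'
#' Summarises a combined DE table (all five standard comparisons bound
#' together) into one row per feature with significance flags and
#' directions for each (reference, timepoint) cell. A comparison is
#' significant when it passes [apply_de_filters()] thresholds.
#'
#' @param de_all DE tibble covering several comparisons (rows carry
#'   `case_*`/`control_*` columns as produced by
#'   [differential_expression()]).
#' @param fc_cutoff,alpha Candidate-filter thresholds.
#' @param control_genotype Genotype of the age-matched reference; the
#'   baseline reference is the case genotype at its first timepoint.
#' @return A tibble with `feature_id` and, per timepoint `TP`, logical
#'   `sig_wt_TP` / numeric `dir_wt_TP` columns plus `sig_base_TP` /
#'   `dir_base_TP` for post-baseline timepoints.
#' @export
temporal_profiles <- function(de_all, fc_cutoff = 1.5, alpha = 0.05,
                              control_genotype = "WT") {
  de <- de_all |>
    dplyr::mutate(
      reference = ifelse(.data$control_genotype == !!control_genotype, "wt", "base"),
      timepoint = .data$case_timepoint,
      sig = abs(.data$signed_fc) >= fc_cutoff & .data$p_adj < alpha,
      dir = sign(.data$signed_fc)
    )
  wide <- de |>
    dplyr::select("feature_id", "reference", "timepoint", "sig", "dir") |>
    tidyr::pivot_wider(
      names_from = c("reference", "timepoint"),
      values_from = c("sig", "dir"),
      names_glue = "{.value}_{reference}_{timepoint}"
    )
  wide
}

sig_col <- function(profiles, ref, tp) {
  col <- sprintf("sig_%s_%s", ref, tp)
  if (!col %in% names(profiles)) return(rep(NA, nrow(profiles)))
  tidyr::replace_na(profiles[[col]], FALSE)
}

#' Classify DE miRNAs by temporal onset
#'
#' Group A holds miRNAs dysregulated before photoreceptor-apoptosis onset:
#' under the default disjunctive rule, significance at P15 against both the
#' age-matched control and the case-genotype P13 baseline, or significance
#' at P13 against the age-matched control (the baseline comparison is
#' undefined at P13). The conjunctive rule additionally requires the P13
#' significance. Group B holds miRNAs dysregulated only after onset:
#' significant at P17 against both references with no filtered-significant
#' result at any earlier stage. The classes are mutually exclusive;
#' everything else is unassigned.
#'
#' @param profiles Output of [temporal_profiles()].
#' @param rule `"disjunctive"` (default) or `"conjunctive"` group-A
#'   reading.
#' @param timepoints Ordered timepoints (first = baseline).
#' @return A tibble `feature_id`, `group` (factor `A`/`B`/`unassigned`).
#' @export
classify_groups <- function(profiles, rule = c("disjunctive", "conjunctive"),
                            timepoints = c("P13", "P15", "P17")) {
  rule <- match.arg(rule)
  tp <- timepoints
  s_wt13 <- sig_col(profiles, "wt", tp[1])
  s_wt15 <- sig_col(profiles, "wt", tp[2])
  s_wt17 <- sig_col(profiles, "wt", tp[3])
  s_b15 <- sig_col(profiles, "base", tp[2])
  s_b17 <- sig_col(profiles, "base", tp[3])
  if (anyNA(c(s_wt13, s_wt15, s_wt17, s_b15, s_b17))) {
    rlang::warn("missing comparison data; affected features left unassigned")
    for (v in c("s_wt13", "s_wt15", "s_wt17", "s_b15", "s_b17")) {
      assign(v, tidyr::replace_na(get(v), FALSE))
    }
  }
  pre_onset_sig <- (s_wt15 & s_b15) | s_wt13
  is_A <- if (rule == "disjunctive") pre_onset_sig else (s_wt15 & s_b15) & s_wt13
  any_previous <- s_wt13 | s_wt15 | s_b15
  is_B <- s_wt17 & s_b17 & !any_previous & !is_A
  tibble::tibble(
    feature_id = profiles$feature_id,
    group = factor(
      dplyr::case_when(is_A ~ "A", is_B ~ "B", TRUE ~ "unassigned"),
      levels = c("A", "B", "unassigned")
    )
  )
}

#' Fold-change trajectory of a feature across comparisons
#'
#' @param de_all Combined DE tibble (all comparisons).
#' @param feature One feature id, tested in every comparison.
#' @param control_genotype Age-matched reference genotype.
#' @return An ordered tibble (`comparison`, `reference`, `timepoint`,
#'   `signed_fc`, `p_adj`) suitable for plotting.
#' @export
track_trajectory <- function(de_all, feature, control_genotype = "WT") {
  rows <- dplyr::filter(de_all, .data$feature_id == feature)
  if (nrow(rows) == 0) stop_mirlag("feature %s not tested in any comparison", feature)
  rows |>
    dplyr::mutate(
      reference = ifelse(.data$control_genotype == !!control_genotype, "wt", "base"),
      timepoint = .data$case_timepoint
    ) |>
    dplyr::arrange(.data$reference, .data$timepoint) |>
    dplyr::select("feature_id", "comparison", "reference", "timepoint",
                  "signed_fc", "p_adj")
}
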