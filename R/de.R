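#' Signed fold change
#'
#' The array-reporting convention: a case/control ratio `r >= 1` is reported
#' as `r`, a ratio below 1 as `-1/r`, so down-regulation appears as a
#' negative magnitude and |signed FC| is always >= 1 (e.g. ratio 0.568 is
#' reported as -1.76-fold).
#'
#' @param mean_case,mean_control Positive linear-scale group means
#'   (vectorized).
#' @return Signed fold changes.
#' @examples
#' signed_fold_change(30, 10) # 3
#' signed_fold_change(10, 17.6) # about -1.76
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop_mirlag("group means must be positive")
  }
  r <- mean_case / mean_control
  ifelse(r >= 1, r, -1 / r)
}

#' Define a two-group comparison
#'
#' @param case,control Length-2 character vectors `c(genotype, timepoint)`.
#' @param label Comparison label; autogenerated if missing.
#' @return A `comparison` object.
#' @export
comparison <- function(case, control, label = NULL) {
  if (identical(case, control)) stop_mirlag("case and control groups must differ")
  if (is.null(label)) {
    label <- if (case[1] != control[1] && case[2] == control[2]) {
      sprintf("%s_vs_%s_%s", case[1], control[1], case[2])
    } else {
      sprintf("%s_%s_vs_%s_%s", case[1], case[2], control[1], control[2])
    }
  }
  structure(list(case = case, control = control, label = label), class = "comparison")
}

#' The standard rd10 comparison set
#'
#' Case-genotype vs age-matched control at every timepoint, plus
#' case-genotype later timepoints vs its own first-timepoint baseline
#' (pre-onset reference).
#'
#' @param genotypes Case and control genotype labels.
#' @param timepoints Ordered timepoints.
#' @return A list of [comparison()] objects.
#' @export
rd10_comparisons <- function(genotypes = c("rd10", "WT"),
                             timepoints = c("P13", "P15", "P17")) {
  case <- genotypes[1]; ctrl <- genotypes[2]
  vs_wt <- purrr::map(timepoints, ~ comparison(c(case, .x), c(ctrl, .x)))
  vs_base <- purrr::map(timepoints[-1], ~ comparison(c(case, .x), c(case, timepoints[1])))
  c(vs_wt, vs_base)
}

# vectorized Welch two-sample t-test on rows of log2 matrices
welch_t_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate: both groups constant
  zero <- se2 == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  list(t = tstat, df = df, p = p, m1 = m1, m2 = m2)
}

#' Per-feature differential expression for one comparison
#'
#' Welch two-sample t-test on log2-transformed signals, Benjamini-Hochberg
#' adjustment across all tested features within the comparison, and signed
#' fold change from the linear group means. Requires >= 2 replicates per
#' side.
#'
#' @param expr Wide (normalized) expression tibble on the linear scale.
#' @param cmp A [comparison()].
#' @return A tibble with one row per feature: `feature_id`, `comparison`,
#'   case/control group labels, linear group means, `log2fc`, `signed_fc`,
#'   `p_raw`, `p_adj`, and `replicate_cv` (the larger linear-scale
#'   coefficient of variation of the two groups).
#' @export
differential_expression <- function(expr, cmp) {
  assert_feature_table(expr)
  meta <- sample_metadata(expr)
  pick <- function(grp) meta$sample_id[meta$genotype == grp[1] & meta$timepoint == grp[2]]
  case_cols <- pick(cmp$case); ctrl_cols <- pick(cmp$control)
  if (length(case_cols) == 0 || length(ctrl_cols) == 0) {
    stop_mirlag("comparison groups not found among samples (%s / %s)",
                paste(cmp$case, collapse = " "), paste(cmp$control, collapse = " "))
  }
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    stop_mirlag("need >= 2 replicates per side")
  }
  m <- expr_matrix(expr)
  xc <- m[, case_cols, drop = FALSE]; xk <- m[, ctrl_cols, drop = FALSE]
  tt <- welch_t_rows(log2(xc), log2(xk))
  mean_case <- rowMeans(xc); mean_ctrl <- rowMeans(xk)
  cv <- function(x) apply(x, 1, stats::sd) / rowMeans(x)
  tibble::tibble(
    feature_id = expr$feature_id,
    comparison = cmp$label,
    case_genotype = cmp$case[1], case_timepoint = cmp$case[2],
    control_genotype = cmp$control[1], control_timepoint = cmp$control[2],
    mean_case = unname(mean_case),
    mean_control = unname(mean_ctrl),
    log2fc = unname(log2(mean_case / mean_ctrl)),
    signed_fc = unname(signed_fold_change(mean_case, mean_ctrl)),
    p_raw = unname(tt$p),
    p_adj = unname(stats::p.adjust(tt$p, method = "BH")),
    replicate_cv = unname(pmax(cv(xc), cv(xk)))
  )
}

#' Apply fold-change and significance candidate filters
#'
#' Retains features with |signed FC| at or above the cutoff and adjusted
#' P below `alpha`. The study's cutoffs are +/-1.5 for miRNAs and +/-1.3
#' for mRNAs, with adjusted P < 0.05.
#'
#' @param de DE result tibble from [differential_expression()].
#' @param fc_cutoff Signed-fold-change magnitude cutoff (>= 1).
#' @param alpha Adjusted-significance level.
#' @return The filtered DE tibble.
#' @export
apply_de_filters <- function(de, fc_cutoff = 1.5, alpha = 0.05) {
  if (fc_cutoff < 1) stop_mirlag("fc_cutoff must be >= 1")
  dplyr::filter(de, abs(.data$signed_fc) >= fc_cutoff, .data$p_adj < alpha)
}

#' Exclude near-background and high-variability features
#'
#' The background level is estimated as the median signal of features
#' flagged absent in every array. A feature is dropped when its median
#' normalized signal falls below `background_margin` times that level, or
#' when its within-group linear-scale coefficient of variation exceeds
#' `cv_max` in either group.
#'
#' @param de DE result tibble.
#' @param expr Wide normalized expression tibble (for median signals and
#'   background estimation).
#' @param calls Matching detection tibble.
#' @param background_margin Multiplier on the estimated background level.
#' @param cv_max Maximum tolerated replicate coefficient of variation.
#' @return The filtered DE tibble.
#' @export
apply_quality_exclusions <- function(de, expr, calls,
                                     background_margin = 1.2, cv_max = 0.5) {
  if (background_margin <= 0 || cv_max <= 0) stop_mirlag("thresholds must be positive")
  m <- expr_matrix(expr)
  callm <- as.matrix(calls[, sample_cols(calls)])[match(expr$feature_id, calls$feature_id), , drop = FALSE]
  absent_everywhere <- rowSums(callm == "P") == 0
  bg <- if (any(absent_everywhere)) {
    stats::median(m[absent_everywhere, , drop = FALSE])
  } else {
    0 # no absent features: nothing can sit near background
  }
  med_signal <- apply(m, 1, stats::median)
  ok_signal <- med_signal[match(de$feature_id, expr$feature_id)] >= background_margin * bg
  dplyr::filter(de, ok_signal, .data$replicate_cv <= cv_max)
}

#' Merge candidate lists from two platforms
#'
#' Set union deduplicated by feature id; a candidate appearing on both
#' platforms with opposite fold-change directions is retained once and
#' flagged.
#'
#' @param list_a,list_b Candidate DE tibbles sharing one feature id space.
#' @return A tibble with one row per candidate, a `platform` column
#'   (`"a"`, `"b"` or `"both"`) and a `direction_conflict` flag.
#' @export
merge_platform_candidates <- function(list_a, list_b) {
  a <- dplyr::mutate(list_a, .platform = "a")
  b <- dplyr::mutate(list_b, .platform = "b")
  dplyr::bind_rows(a, b) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      platform = if (dplyr::n_distinct(.data$.platform) > 1) "both" else .data$.platform[1],
      direction_conflict = dplyr::n_distinct(sign(.data$signed_fc)) > 1,
      signed_fc = .data$signed_fc[1],
      .groups = "drop"
    )
}
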