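#' Select stable reference assays for Ct normalization
#'
#' Ranks candidate reference features by the standard deviation of their
#' mean Ct (over technical replicates) across biological samples and
#' returns the lowest-variability pair (or `n_refs`), together with all
#' pairwise squared Pearson correlations of the candidates' Ct profiles -
#' the study picked miR-26a/miR-191-5p (miRNA) and Gapdh/Tubb5/beta-Act
#' (mRNA) this way, checking the references correlate strongly among
#' themselves.
#'
#' @param ct_table Long Ct tibble.
#' @param candidates Candidate reference feature ids (>= 2, complete Ct
#'   coverage across all samples).
#' @param n_refs Number of references to return.
#' @return A `ref_selection`: list with `references`, `stability` tibble
#'   (`feature_id`, `sd_ct`, `rank`) and the pairwise `r2` matrix.
#' @export
select_references <- function(ct_table, candidates, n_refs = 2) {
  if (length(candidates) < 2) stop_mirlag("need >= 2 reference candidates")
  sub <- dplyr::filter(ct_table, .data$feature_id %in% candidates)
  per_sample <- sub |>
    dplyr::group_by(.data$feature_id, .data$sample_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  cover <- per_sample |>
    dplyr::count(.data$feature_id)
  n_samples <- dplyr::n_distinct(ct_table$sample_id)
  missing <- setdiff(candidates, cover$feature_id[cover$n == n_samples])
  if (length(missing) > 0) {
    stop_mirlag("incomplete Ct coverage for candidate(s): %s",
                paste(missing, collapse = ", "))
  }
  stability <- per_sample |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(sd_ct = stats::sd(.data$ct), .groups = "drop") |>
    dplyr::arrange(.data$sd_ct) |>
    dplyr::mutate(rank = dplyr::row_number())
  profile <- per_sample |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "ct") |>
    dplyr::select(dplyr::all_of(candidates)) |>
    as.matrix()
  # a zero-variance candidate has undefined correlation; report NA quietly
  r2 <- suppressWarnings(stats::cor(profile)^2)
  structure(
    list(
      references = stability$feature_id[seq_len(min(n_refs, nrow(stability)))],
      stability = stability,
      r2 = r2
    ),
    class = "ref_selection"
  )
}

#' @export
print.ref_selection <- function(x, ...) {
  cat("<ref_selection> chosen:", paste(x$references, collapse = ", "), "\n")
  print(x$stability)
  invisible(x)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per biological sample, the target's mean technical-replicate Ct is
#' normalized by the arithmetic mean of the reference Cts (equivalent to
#' the geometric mean of the linear reference quantities), giving a
#' per-sample delta-Ct. Delta-delta-Ct is the case-group mean minus the
#' control-group mean; the linear ratio is `efficiency^(-ddct)` (assumed
#' amplification efficiency 2, i.e. perfect doubling) and is reported as a
#' signed fold change. The P value is a Welch two-sample t-test on the
#' per-sample delta-Ct values.
#'
#' @param ct_table Long Ct tibble.
#' @param target Target feature id.
#' @param references Reference feature ids.
#' @param case_samples,control_samples Biological sample ids for the two
#'   groups.
#' @param efficiency Amplification efficiency (ratio base).
#' @return A one-row tibble: `feature_id`, `ddct`, `ratio`, `signed_fc`,
#'   `p`.
#' @export
ddct_fold_change <- function(ct_table, target, references,
                             case_samples, control_samples, efficiency = 2) {
  if (length(case_samples) == 0 || length(control_samples) == 0) {
    stop_mirlag("empty sample group")
  }
  samples <- c(case_samples, control_samples)
  sub <- ct_table |>
    dplyr::filter(.data$feature_id %in% c(target, references),
                  .data$sample_id %in% samples) |>
    dplyr::group_by(.data$feature_id, .data$sample_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  have <- sub |>
    dplyr::count(.data$feature_id)
  need <- c(target, references)
  missing <- need[!(need %in% have$feature_id[have$n == length(samples)])]
  if (length(missing) > 0) {
    stop_mirlag("missing Ct measurements for: %s", paste(missing, collapse = ", "))
  }
  dct <- sub |>
    dplyr::mutate(role = ifelse(.data$feature_id == target, "target", "reference")) |>
    dplyr::group_by(.data$sample_id, .data$role) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "ct") |>
    dplyr::mutate(dct = .data$target - .data$reference)
  dct_case <- dct$dct[dct$sample_id %in% case_samples]
  dct_ctrl <- dct$dct[dct$sample_id %in% control_samples]
  ddct <- mean(dct_case) - mean(dct_ctrl)
  ratio <- efficiency^(-ddct)
  p <- if (length(dct_case) >= 2 && length(dct_ctrl) >= 2 &&
           (stats::sd(dct_case) > 0 || stats::sd(dct_ctrl) > 0)) {
    stats::t.test(dct_case, dct_ctrl)$p.value
  } else if (isTRUE(all.equal(mean(dct_case), mean(dct_ctrl)))) {
    1
  } else {
    0 # zero within-group variance with a group difference
  }
  tibble::tibble(
    feature_id = target,
    ddct = ddct,
    ratio = ratio,
    signed_fc = ifelse(ratio >= 1, ratio, -1 / ratio),
    p = p
  )
}

#' Confront array candidates with their qPCR measurements
#'
#' A candidate is confirmed when its qPCR fold change has the same sign as
#' its array fold change and its qPCR P value is below `alpha`.
#' Confirmation counts and percentages are reported separately for up- and
#' down-regulated candidates (direction taken from the array fold change)
#' and overall.
#'
#' @param array_de Candidate tibble with `feature_id` and array
#'   `signed_fc`.
#' @param qpcr_fcs Tibble of [ddct_fold_change()] rows (`feature_id`,
#'   `signed_fc`, `p`).
#' @param alpha qPCR significance level; set to `1` to confirm on
#'   direction alone.
#' @return A `validation_summary`: list with per-candidate tibble
#'   `candidates` and aggregate tibble `summary` (`direction`, `tested`,
#'   `confirmed`, `pct_confirmed`).
#' @export
validate_candidates <- function(array_de, qpcr_fcs, alpha = 0.05) {
  arr <- dplyr::select(array_de, "feature_id", array_fc = "signed_fc")
  qp <- dplyr::select(qpcr_fcs, "feature_id", qpcr_fc = "signed_fc", qpcr_p = "p")
  missing <- c(setdiff(arr$feature_id, qp$feature_id),
               setdiff(qp$feature_id, arr$feature_id))
  if (length(missing) > 0) {
    stop_mirlag("candidate(s) missing one measurement: %s",
                paste(unique(missing), collapse = ", "))
  }
  candidates <- dplyr::inner_join(arr, qp, by = "feature_id") |>
    dplyr::mutate(
      direction = ifelse(.data$array_fc > 0, "up", "down"),
      confirmed = sign(.data$array_fc) == sign(.data$qpcr_fc) & .data$qpcr_p < alpha
    )
  by_dir <- candidates |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(tested = dplyr::n(), confirmed = sum(.data$confirmed), .groups = "drop")
  overall <- tibble::tibble(
    direction = "overall",
    tested = nrow(candidates),
    confirmed = sum(candidates$confirmed)
  )
  summary <- dplyr::bind_rows(by_dir, overall) |>
    dplyr::mutate(pct_confirmed = 100 * .data$confirmed / .data$tested)
  structure(list(candidates = candidates, summary = summary),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation_summary>\n")
  print(x$summary)
  invisible(x)
}
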