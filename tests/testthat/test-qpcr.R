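make_ct <- function(values, samples, feature, n_tech = 1) {
  tidyr::expand_grid(sample_id = samples, tech_rep = seq_len(n_tech)) |>
    dplyr::mutate(feature_id = feature, ct = rep(values, each = n_tech)) |>
    dplyr::select(feature_id, sample_id, tech_rep, ct)
}

test_that("reference selection ranks by Ct stability and reports r-squared", {
  samples <- c(sprintf("rd10_P15_%d", 1:3), sprintf("WT_P15_%d", 1:3))
  ct <- dplyr::bind_rows(
    make_ct(rep(20, 6), samples, "stable"),                  # zero variance
    make_ct(c(20, 21, 22, 23, 24, 25), samples, "drift"),    # high variance
    make_ct(c(20.0, 20.2, 19.9, 20.1, 20.0, 19.8), samples, "wobble")
  )
  sel <- select_references(ct, c("stable", "drift", "wobble"))
  expect_equal(sel$stability$feature_id[1], "stable")
  expect_equal(sel$references, c("stable", "wobble"))
  # direct-formula oracle for the ranking and r2
  sds <- c(stable = 0, drift = sd(20:25), wobble = sd(c(20, 20.2, 19.9, 20.1, 20, 19.8)))
  expect_equal(sel$stability$sd_ct, unname(sort(sds)))
  expect_equal(sel$r2["drift", "wobble"],
               cor(20:25, c(20, 20.2, 19.9, 20.1, 20, 19.8))^2)
  # identical profiles give r2 = 1
  ct2 <- dplyr::bind_rows(make_ct(20:25, samples, "a"), make_ct(20:25, samples, "b"))
  expect_equal(select_references(ct2, c("a", "b"))$r2["a", "b"], 1)
  # incomplete coverage errors
  expect_error(select_references(dplyr::bind_rows(make_ct(rep(20, 6), samples, "x"),
                                                  make_ct(rep(21, 5), samples[-1], "y")),
                                 c("x", "y")), "coverage")
})

test_that("ddCt closed forms hold", {
  samples <- c(sprintf("rd10_P15_%d", 1:3), sprintf("WT_P15_%d", 1:3))
  case <- samples[1:3]; ctrl <- samples[4:6]
  ref <- make_ct(rep(20, 6), samples, "ref")

  # ddCt = 0 -> FC 1
  t0 <- make_ct(rep(25, 6), samples, "t")
  r0 <- ddct_fold_change(dplyr::bind_rows(t0, ref), "t", "ref", case, ctrl)
  expect_equal(r0$signed_fc, 1)
  expect_equal(r0$p, 1)

  # ddCt = -1 -> +2; ddCt = +1 -> -2
  t1 <- make_ct(c(24, 24, 24, 25, 25, 25), samples, "t")
  expect_equal(ddct_fold_change(dplyr::bind_rows(t1, ref), "t", "ref", case, ctrl)$signed_fc, 2)
  t2 <- make_ct(c(26, 26, 26, 25, 25, 25), samples, "t")
  expect_equal(ddct_fold_change(dplyr::bind_rows(t2, ref), "t", "ref", case, ctrl)$signed_fc, -2)

  expect_error(ddct_fold_change(dplyr::bind_rows(t1, ref), "t", "ref", character(), ctrl), "empty")
  expect_error(ddct_fold_change(dplyr::bind_rows(t1, ref), "t", "missing-ref", case, ctrl), "missing")
})

test_that("normalization cancels sample-wide Ct offsets only when shared", {
  samples <- c(sprintf("rd10_P15_%d", 1:3), sprintf("WT_P15_%d", 1:3))
  case <- samples[1:3]; ctrl <- samples[4:6]
  target <- make_ct(c(24, 24.5, 24.2, 25, 25.1, 24.9), samples, "t")
  ref <- make_ct(c(20, 20.2, 19.9, 20.1, 20.3, 20.0), samples, "ref")
  base <- ddct_fold_change(dplyr::bind_rows(target, ref), "t", "ref", case, ctrl)
  # adding a constant to one sample's target AND reference leaves ddCt unchanged
  shift_both <- dplyr::bind_rows(target, ref) |>
    dplyr::mutate(ct = ct + ifelse(sample_id == samples[1], 3, 0))
  expect_equal(ddct_fold_change(shift_both, "t", "ref", case, ctrl)$ddct, base$ddct)
  # shifting only the target changes it
  shift_t <- dplyr::bind_rows(
    dplyr::mutate(target, ct = ct + ifelse(sample_id == samples[1], 3, 0)), ref
  )
  expect_false(isTRUE(all.equal(ddct_fold_change(shift_t, "t", "ref", case, ctrl)$ddct,
                                base$ddct)))
})

test_that("noise-free synthetic Ct recovers planted signed FC to machine tolerance", {
  cfg <- sim_config(n_mirna = 20, n_mrna = 30, frac_groupA = 0.2, frac_groupB = 0.2,
                    targets_per_mirna = 1, seed = 17)
  sim <- simulate_expression(cfg)
  tr <- sim$truth$de_mirnas
  ct <- simulate_qpcr(cfg, sim$truth, tr$feature_id, ct_noise_sd = 0)
  smeta <- parse_sample_ids(unique(ct$sample_id))
  for (i in seq_len(nrow(tr))) {
    tp <- if (tr$group[i] == "A") "P15" else "P17"
    res <- ddct_fold_change(
      ct, tr$feature_id[i], c("ref-1", "ref-2"),
      case_samples = smeta$sample_id[smeta$genotype == "rd10" & smeta$timepoint == tp],
      control_samples = smeta$sample_id[smeta$genotype == "WT" & smeta$timepoint == tp]
    )
    planted <- tr[[paste0("lfc_", tp)]][i]
    want <- ifelse(planted >= 0, 2^planted, -2^(-planted))
    expect_equal(res$signed_fc, want, tolerance = 1e-9)
  }
})

test_that("validation summary arithmetic and confirmation rule", {
  arr <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        signed_fc = c(2, 3, -2, -3))
  qp <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                       signed_fc = c(2.5, -1.5, -1.8, -2.2),
                       p = c(0.01, 0.01, 0.01, 0.2))
  v <- validate_candidates(arr, qp)
  cand <- tidy(v)
  # a: same sign significant -> confirmed; b: sign flip -> no;
  # c: confirmed; d: same sign but p 0.2 -> no
  expect_equal(cand$confirmed[match(c("a", "b", "c", "d"), cand$feature_id)],
               c(TRUE, FALSE, TRUE, FALSE))
  s <- v$summary
  expect_equal(s$pct_confirmed[s$direction == "up"], 50)
  expect_equal(s$pct_confirmed[s$direction == "down"], 50)
  expect_equal(s$tested[s$direction == "overall"], 4)
  # direction-only criterion via alpha = 1
  v2 <- validate_candidates(arr, qp, alpha = 1)
  expect_equal(sum(tidy(v2)$confirmed), 3)
  # all confirmed -> 100% in every stratum
  v3 <- validate_candidates(arr, dplyr::mutate(qp, signed_fc = arr$signed_fc, p = 0.001))
  expect_true(all(v3$summary$pct_confirmed == 100))
  expect_error(validate_candidates(arr[1:3, ], qp), "missing")
})

test_that("validation confirms planted candidates and rejects nulls on synthetic Ct data", {
  cfg <- sim_config(n_mirna = 40, n_mrna = 30, frac_groupA = 0.25, frac_groupB = 0.25,
                    targets_per_mirna = 1, frac_background = 0, seed = 23)
  sim <- simulate_expression(cfg)
  tr <- sim$truth$de_mirnas
  nulls <- setdiff(sim$mirna_expr$feature_id, tr$feature_id)
  ct <- simulate_qpcr(cfg, sim$truth, c(tr$feature_id, nulls))
  smeta <- parse_sample_ids(unique(ct$sample_id))
  run_ddct <- function(ids, tp) {
    purrr::map_dfr(ids, ~ ddct_fold_change(
      ct, .x, c("ref-1", "ref-2"),
      case_samples = smeta$sample_id[smeta$genotype == "rd10" & smeta$timepoint == tp],
      control_samples = smeta$sample_id[smeta$genotype == "WT" & smeta$timepoint == tp]
    ))
  }
  planted_q <- run_ddct(tr$feature_id, "P17")
  # planted features confirmed at a high rate (array FC taken as the truth direction)
  arr <- tibble::tibble(feature_id = tr$feature_id,
                        signed_fc = ifelse(tr$direction > 0, 2, -2))
  v <- validate_candidates(arr, planted_q)
  expect_gte(v$summary$pct_confirmed[v$summary$direction == "overall"], 80)
  # null features confirm at ~alpha
  null_q <- run_ddct(nulls, "P17")
  arr0 <- tibble::tibble(feature_id = nulls, signed_fc = 2)
  v0 <- validate_candidates(arr0, null_q)
  expect_lte(v0$summary$confirmed[v0$summary$direction == "overall"], ceiling(0.15 * length(nulls)))
})
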