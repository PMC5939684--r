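test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config(n_mirna = 40, n_mrna = 80, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$mirna_expr, b$mirna_expr)
  expect_identical(a$mrna_expr, b$mrna_expr)
  expect_identical(a$mirna_calls, b$mirna_calls)
  expect_identical(a$truth$de_mirnas, b$truth$de_mirnas)
  c <- simulate_expression(sim_config(n_mirna = 40, n_mrna = 80, seed = 12))
  expect_false(identical(a$mirna_expr, c$mirna_expr))
})

test_that("matrix shape and planted-group templates follow the study design", {
  cfg <- sim_config(n_mirna = 50, n_mrna = 100, frac_groupA = 0.1, frac_groupB = 0.1,
                    noise_sd = 0, frac_background = 0.1, seed = 3)
  sim <- simulate_expression(cfg)
  expect_equal(ncol(sim$mirna_expr) - 1, 2 * 3 * 3) # genotypes x timepoints x reps
  tr <- sim$truth$de_mirnas
  expect_true(all(tr$lfc_P15[tr$group == "A"] != 0))
  expect_true(all(tr$lfc_P17[tr$group == "A"] != 0))
  expect_true(all(tr$lfc_P13[tr$group == "A"] == 0)) # optional P13 effect off by default
  expect_true(all(tr$lfc_P15[tr$group == "B"] == 0))
  expect_true(all(tr$lfc_P17[tr$group == "B"] != 0))

  # with zero noise the planted log2 ratios are exactly recovered, and
  # non-DE features share means across genotypes
  m <- log2(expr_matrix(sim$mirna_expr))
  meta <- sample_metadata(sim$mirna_expr)
  grab <- function(f, g, tp) mean(m[f, meta$sample_id[meta$genotype == g & meta$timepoint == tp]])
  a1 <- tr$feature_id[tr$group == "A"][1]
  expect_equal(grab(a1, "rd10", "P15") - grab(a1, "WT", "P15"), tr$lfc_P15[tr$feature_id == a1])
  null_f <- setdiff(sim$mirna_expr$feature_id, c(tr$feature_id, sim$truth$background_features))[1]
  expect_equal(grab(null_f, "rd10", "P15"), grab(null_f, "WT", "P15"))
})

test_that("no planted effects means no DE ground truth", {
  cfg <- sim_config(n_mirna = 30, n_mrna = 40, frac_groupA = 0, frac_groupB = 0, seed = 5)
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$truth$de_mirnas), 0)
  expect_equal(nrow(sim$truth$true_targets), 0)
})

test_that("every true regulation has a target shifting in the opposite direction", {
  sm <- small_sim()
  tr <- sm$sim$truth
  joined <- dplyr::inner_join(tr$true_targets, tr$de_mirnas,
                              by = c(mirna_id = "feature_id"))
  expect_true(all(sign(joined$gene_lfc) * joined$direction == -1))
  expect_true(all(joined$response_timepoint == "P17"))
})

test_that("background features are flagged absent at the detection model's rate", {
  cfg <- sim_config(n_mirna = 300, n_mrna = 50, frac_groupA = 0, frac_groupB = 0,
                    frac_background = 0.5, seed = 9)
  sim <- simulate_expression(cfg)
  bg <- intersect(sim$truth$background_features, sim$mirna_calls$feature_id)
  callm <- as.matrix(sim$mirna_calls[match(bg, sim$mirna_calls$feature_id), -1])
  n_draws <- length(callm)
  n_present <- sum(callm == "P")
  # present with probability 0.05 by construction; binomial 99.9% bounds
  bounds <- qbinom(c(0.0005, 0.9995), n_draws, 0.05)
  expect_gte(n_present, bounds[1])
  expect_lte(n_present, bounds[2])
  # expressed features are essentially always present
  expr_f <- setdiff(sim$mirna_expr$feature_id, bg)
  callex <- as.matrix(sim$mirna_calls[match(expr_f, sim$mirna_calls$feature_id), -1])
  expect_gt(mean(callex == "P"), 0.99)
})

test_that("planted group-A effect is detectable by a raw t-test in >=80% of repetitions", {
  # Monte-Carlo power oracle at the stated parameters: effect 1.5 log2,
  # noise 0.25, n = 3/side
  hits <- vapply(1:200, function(s) {
    set.seed(7000 + s)
    x <- rnorm(3, 1.5, 0.25)
    y <- rnorm(3, 0, 0.25)
    t.test(x, y)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("prediction table construction follows its rules", {
  sm <- small_sim()
  pred <- simulate_prediction_table(sm$cfg, sm$sim$truth)
  tt <- sm$sim$truth$true_targets
  true_keys <- paste(tt$mirna_id, tt$gene_id)
  pred_keys <- paste(pred$mirna_id, pred$gene_id)
  expect_true(all(true_keys %in% pred_keys))
  expect_true(all(pred$n_algorithms[pred_keys %in% true_keys] >= 2))
  expect_identical(pred, simulate_prediction_table(sm$cfg, sm$sim$truth))

  # rate 0 gives exactly the true targets
  cfg0 <- sim_config(n_mirna = 20, n_mrna = 60, frac_groupA = 0.1, frac_groupB = 0.1,
                     targets_per_mirna = 2, false_prediction_rate = 0, seed = 2)
  sim0 <- simulate_expression(cfg0)
  p0 <- simulate_prediction_table(cfg0, sim0$truth)
  expect_setequal(paste(p0$mirna_id, p0$gene_id),
                  paste(sim0$truth$true_targets$mirna_id, sim0$truth$true_targets$gene_id))
})

test_that("spurious prediction count stays within binomial bounds", {
  cfg <- sim_config(n_mirna = 10, n_mrna = 100, frac_groupA = 0.1, frac_groupB = 0,
                    targets_per_mirna = 1, false_prediction_rate = 0.001, seed = 31)
  sim <- simulate_expression(cfg)
  pred <- simulate_prediction_table(cfg, sim$truth)
  n_true <- nrow(sim$truth$true_targets)
  n_spurious <- nrow(pred) - n_true
  bounds <- qbinom(c(0.005, 0.995), 10 * 100 - n_true, 0.001)
  expect_gte(n_spurious, bounds[1])
  expect_lte(n_spurious, bounds[2])
})

test_that("qPCR Ct model reproduces planted ratios", {
  cfg <- sim_config(n_mirna = 20, n_mrna = 30, frac_groupA = 0.2, frac_groupB = 0,
                    effect_log2 = 2, targets_per_mirna = 1, p_up = 1, seed = 13)
  sim <- simulate_expression(cfg)
  tr <- sim$truth$de_mirnas
  up <- tr$feature_id[tr$direction == 1][1]
  ct <- simulate_qpcr(cfg, sim$truth, up, ct_noise_sd = 0)

  # reference Ct is invariant across samples at zero noise
  ref <- dplyr::filter(ct, feature_id == "ref-1")
  expect_equal(sd(ref$ct), 0)

  # a 4-fold up feature gives ddCt exactly -2
  smeta <- parse_sample_ids(unique(ct$sample_id))
  res <- ddct_fold_change(
    ct, up, c("ref-1", "ref-2"),
    case_samples = smeta$sample_id[smeta$genotype == "rd10" & smeta$timepoint == "P15"],
    control_samples = smeta$sample_id[smeta$genotype == "WT" & smeta$timepoint == "P15"]
  )
  expect_equal(res$ddct, -2)
  expect_equal(res$signed_fc, 4)

  expect_error(simulate_qpcr(cfg, sim$truth, "no-such-feature"), "unknown feature")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_mirna = 0), "counts")
  expect_error(sim_config(frac_groupA = 0.7, frac_groupB = 0.5), "frac")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(timepoints = c("P13", "P13", "P15")), "timepoints")
})
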