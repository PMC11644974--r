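spec40 <- function(seed = 1) {
  model_spec("gradient_boosted_trees", params = list(iterations = 40),
             seed = seed)
}

test_that("ablation on identical column sets is an exact no-op", {
  tab <- make_synthetic_table(n_infants = 8, windows_per_infant = 20, seed = 1)
  folds <- make_group_folds(tab$windows$infant_id, 5, seed = 1)
  ref <- posture_cv(tab, spec40(), folds = folds)
  # drop a group that has no columns in the table
  tab_nocorr <- subset_feature_table(tab,
                                     cols = which(tab$descriptors$group != "correlation"))
  rep_noop <- ablate(tab_nocorr, spec40(), folds, mode = "without",
                     group = "correlation", reference = posture_cv(tab_nocorr,
                                                                   spec40(),
                                                                   folds = folds))
  expect_equal(rep_noop$delta_f1_pct, rep(0, 5))
  expect_error(ablate(tab_nocorr, spec40(), folds, mode = "only",
                      group = "correlation"), "zero feature columns")
})

test_that("keep-only ablations over all groups partition the column set", {
  tab <- make_synthetic_table(n_infants = 6, windows_per_infant = 10, seed = 3)
  groups <- c("statistical", "frequency", "summary", "difference", "correlation")
  idx <- unlist(lapply(groups, function(g) which(tab$descriptors$group == g)))
  expect_setequal(idx, seq_len(ncol(tab$values)))
  expect_equal(length(idx), ncol(tab$values))
})

test_that("ablation recovers where the class signal lives", {
  tab <- make_synthetic_table(n_infants = 10, windows_per_infant = 30, seed = 5,
                              signal_cells = list(c("statistical", "acc_lp")))
  folds <- make_group_folds(tab$windows$infant_id, 5, seed = 1)
  ref <- posture_cv(tab, spec40(), folds = folds)
  only_stat <- ablate(tab, spec40(), folds, mode = "only", group = "statistical",
                      reference = ref)
  only_freq <- ablate(tab, spec40(), folds, mode = "only", group = "frequency",
                      reference = ref)
  expect_lt(max(abs(only_stat$delta_f1_pct)), 2)
  expect_lt(max(only_freq$delta_f1_pct), -20)
})

test_that("SHAP group sums exactly partition the total attribution", {
  tab <- make_synthetic_table(n_infants = 8, windows_per_infant = 20, seed = 6)
  folds <- make_group_folds(tab$windows$infant_id, 5, seed = 2)
  cv <- posture_cv(tab, spec40(seed = 2), folds = folds)
  rep <- shap_group_importance(cv, tab)
  per_feature <- attr(rep, "per_feature")
  expect_lt(abs(sum(rep$shap_sum) - sum(per_feature)), 1e-9)
  expect_equal(rep$shap_mean, rep$shap_sum / rep$n_features)

  # single-feature model: its cell's sum is the total
  tab1 <- subset_feature_table(tab, cols = 1L)
  cv1 <- posture_cv(tab1, spec40(seed = 2), folds = folds)
  rep1 <- shap_group_importance(cv1, tab1)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$shap_sum, sum(attr(rep1, "per_feature")))
})

test_that("SHAP attribution concentrates on the signal-carrying group", {
  wins <- 0
  for (s in 1:10) {
    tab <- make_synthetic_table(n_infants = 6, windows_per_infant = 15,
                                seed = 100 + s,
                                signal_cells = list(c("difference", "acc_lp")))
    folds <- make_group_folds(tab$windows$infant_id, 5, seed = s)
    cv <- posture_cv(tab, spec40(seed = s), folds = folds)
    rep <- shap_group_importance(cv, tab)
    sig <- rep$shap_sum[rep$group == "difference" & rep$signal == "acc_lp"]
    noise <- rep$shap_sum[rep$group == "frequency" & rep$signal == "acc_lp"]
    wins <- wins + (sig > noise)
  }
  expect_equal(wins, 10)
})

test_that("the Friedman statistic and BH ladder match hand computations", {
  # 5 blocks x 3 treatments, one treatment always best: chi^2_F = 10
  m <- matrix(c(3, 2, 1), 5, 3, byrow = TRUE) +
    matrix(rep(c(0, 0.001, 0.002), each = 5), 5)  # strict within-block order
  m <- matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  scores <- list(Supine = m)
  res <- friedman_fdr(scores)
  expect_equal(res$statistic, 10, tolerance = 1e-9)
  expect_equal(res$p, stats::pchisq(10, 2, lower.tail = FALSE), tolerance = 1e-9)

  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH") <= 0.05,
               rep(TRUE, 3))

  # identical scores across treatments: no evidence of a difference
  same <- matrix(5, 5, 3) + matrix(rnorm(5, sd = 1e-9), 5, 3)  # ties by block
  res_same <- friedman_fdr(list(A = matrix(rep(runif(5), 3), 5, 3)))
  expect_equal(res_same$statistic, 0)
  expect_equal(res_same$p, 1)

  # rank-based: invariant under monotone transformation
  set.seed(2)
  r <- matrix(runif(15), 5, 3)
  expect_equal(friedman_fdr(list(A = r))$p,
               friedman_fdr(list(A = exp(3 * r)))$p)
})

test_that("sensor-subset comparison reuses folds and reports per-set F1", {
  sessions <- make_cohort(n_infants = 6, duration = 24, seed = 3,
                          locations = c("trunk_a", "leg_left", "leg_right",
                                        "arm_left"))
  sessions <- lapply(sessions, preprocess_session)
  cmp <- compare_sensor_sets(sessions, spec40(), seed = 1,
                             sets = list(trunk = "trunk_a",
                                         trunk_legs = c("trunk_a", "leg_left",
                                                        "leg_right"),
                                         trunk_legs_arms = c("trunk_a", "leg_left",
                                                             "leg_right", "arm_left")))
  expect_equal(dim(cmp$mean_f1), c(3, 5))
  expect_equal(nrow(cmp$tests), 5)
  expect_true(all(cmp$tests$p_adj >= cmp$tests$p - 1e-12, na.rm = TRUE))
  # identical fold assignment across the three runs
  expect_identical(cmp$cv[[1]]$fold_assignment, cmp$cv[[3]]$fold_assignment)
})
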