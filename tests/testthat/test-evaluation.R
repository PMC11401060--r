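# evaluation: metrics, grouped CV, leave-one-protein-out, cutoff
# calibration, rank tests.

test_that("compute_metrics matches hand arithmetic and edge cases", {
  y <- c(rep(1, 5), rep(0, 5))
  p_perfect <- c(rep(1, 5), rep(0, 5))
  m <- compute_metrics(y, p_perfect)
  expect_equal(m$mcc, 1)
  expect_equal(m$bacc, 1)
  expect_equal(m$auc, 1)
  m_all_pos <- compute_metrics(y, rep(1, 10))
  expect_equal(m_all_pos$bacc, 0.5)
  expect_equal(m_all_pos$specificity, 0)
  # TP=3 FP=1 TN=4 FN=2
  labels <- c(rep("Disease-causing", 5), rep("Neutral", 5))
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05)
  m2 <- compute_metrics(labels, probs)
  expect_equal(unname(m2$counts), c(3, 1, 4, 2))
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$sensitivity, 0.6)
  expect_equal(m2$mcc, 10 / sqrt(600))
  # single-class labels: AUC undefined, the rest still computed
  m3 <- compute_metrics(rep(1, 4), c(0.9, 0.8, 0.2, 0.1))
  expect_true(is.na(m3$auc))
  expect_equal(m3$sensitivity, 0.5)
})

test_that("AUC is invariant under strictly monotone probability transforms", {
  withr::with_seed(31, {
    for (i in 1:10) {
      y <- rbinom(30, 1, 0.4)
      if (length(unique(y)) < 2) next
      p <- runif(30)
      a1 <- compute_metrics(y, p)$auc
      a2 <- compute_metrics(y, p^3)$auc
      a3 <- compute_metrics(y, plogis(scale(p)[, 1]))$auc
      expect_equal(a1, a2)
      expect_equal(a1, a3)
    }
  })
})

test_that("kfold_cv splits by site, is seeded, and learns the planted rule", {
  synth <- synth_dataset(synth_preset("separable", seed = 41))
  fm <- cheap_matrix(synth$dataset)
  cfg <- model_config(n_estimators = 30)
  r1 <- kfold_cv(fm, k = 5, cfg, seed = 9)
  r2 <- kfold_cv(fm, k = 5, cfg, seed = 9)
  expect_identical(attr(r1, "folds"), attr(r2, "folds"))
  expect_identical(r1$auc, r2$auc)
  expect_gte(r1$auc, 0.9)
  fold <- attr(r1, "folds")
  groups <- paste(fm$proteins, fm$positions)
  expect_true(all(vapply(split(fold, groups), function(f) {
    length(unique(f)) == 1
  }, logical(1))))
  expect_error(kfold_cv(fm, k = 1, cfg), "at least 2")
  expect_error(kfold_cv(fm, k = 10000, cfg), "exceeds")
})

test_that("leave-one-protein-out holds out whole proteins", {
  # seed chosen so every protein carries both classes
  config <- synth_config(seed = 46, epsilon = 0,
                         shifted_protein = "SYN3")
  fm <- cheap_matrix(synth_dataset(config)$dataset)
  cfg <- model_config(n_estimators = 30)
  reports <- leave_one_protein_out(fm, cfg)
  expect_setequal(names(reports), c("SYN1", "SYN2", "SYN3"))
  # the protein with the inverted rule transfers worse than in-sample fit
  in_sample <- compute_metrics(
    fm$labels[fm$proteins == "SYN3"],
    predict(train(pathomiss:::subset_matrix(
      fm, which(fm$proteins == "SYN3")), cfg),
      pathomiss:::subset_matrix(fm, which(fm$proteins == "SYN3"))))
  expect_lt(reports$SYN3$accuracy, in_sample$accuracy)
  one <- pathomiss:::subset_matrix(fm, which(fm$proteins == "SYN1"))
  expect_error(leave_one_protein_out(one, cfg), "two proteins")
})

test_that("optimize_cutoff scans midpoints, honors orientation and ties", {
  res <- optimize_cutoff(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1), "high")
  expect_equal(res$cutoff, 0.5)
  expect_equal(res$mcc, 1)
  res_low <- optimize_cutoff(c(0.1, 0.4, 0.6, 0.9), c(1, 1, 0, 0), "low")
  expect_equal(res_low$cutoff, 0.5)
  expect_equal(res_low$mcc, 1)
  expect_error(optimize_cutoff(rep(1, 5), c(0, 1, 0, 1, 0)), "constant")
  expect_error(optimize_cutoff(1:5, rep(1, 5)), "both classes")
  # published fixed cutoffs remain usable downstream: thresholding SIFT at
  # 0.05 (low = pathogenic) reproduces its confusion matrix
  scores <- c(0.01, 0.04, 0.2, 0.8)
  labels <- c(1, 1, 0, 0)
  pred <- scores < 0.05
  expect_equal(pred, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("compare_groups is a two-tailed rank-sum test", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  sep <- compare_groups(rnorm(20, 10), rnorm(20, -10))
  expect_lt(sep$p_value, 1e-5)
  expect_true(sep$significant)
  a <- c(5, 1, 7, 3, 9)
  b <- c(2, 8, 4, 6)
  expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  # agrees with the reference implementation by construction
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  expect_equal(compare_groups(a, b)$p_value, wt$p.value)
})
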