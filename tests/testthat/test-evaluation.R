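test_that("classification metrics follow their standard definitions", {
  y <- rep(c("pos", "neg"), c(4, 6))
  expect_equal(compute_metric(y, y, "accuracy"), 1)
  expect_equal(compute_metric(y, y, "f1"), 1)

  # TP = 3, FP = 1, FN = 1, TN = 5
  pred <- c("pos", "pos", "pos", "neg", "pos", "neg", "neg", "neg", "neg", "neg")
  expect_equal(compute_metric(y, pred, "precision"), 0.75)
  expect_equal(compute_metric(y, pred, "recall"), 0.75)
  expect_equal(compute_metric(y, pred, "accuracy"), 0.8)
  expect_equal(compute_metric(y, pred, "f1"), 0.75)

  # tied scores give AUC 1/2; accuracy is exactly 1 - errors/n
  expect_equal(compute_metric(y, rep(1, 10), "auc"), 0.5)
  expect_equal(compute_metric(y, pred, "accuracy"), 1 - 2 / 10)
  expect_error(compute_metric(rep("pos", 5), stats::rnorm(5), "auc"),
               class = "btr_degenerate_error")

  set.seed(5)
  sc <- stats::rnorm(30)
  yy <- ifelse(sc + stats::rnorm(30) > 0, "pos", "neg")
  # AUC via rank statistic equals explicit pair counting
  pos <- yy == "pos"
  pairs <- outer(sc[pos], sc[!pos], function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(compute_metric(yy, sc, "auc"), mean(pairs))
})

test_that("Mann-Whitney ranking orders by association and calibrates on nulls", {
  d <- make_planted(p = 20, n = 40, planted = 1, effect = 100, seed = 61)
  rk <- mann_whitney_rank(d$m, d$y)
  expect_equal(rk$feature[1], "f001")
  expect_equal(rk$direction[1], 1L)

  # constant feature: U/(n1 n2) = 0.5
  v <- d$m$values
  v["f005", ] <- 0.01
  m2 <- btrsign:::new_abundance(v, "relative")
  rk2 <- mann_whitney_rank(m2, d$y)
  expect_equal(rk2$auc[rk2$feature == "f005"], 0.5)

  # label-permuted data: p-values approximately uniform (KS test)
  set.seed(62)
  mnull <- make_abundance(500, 60, seed = 63)
  ynull <- make_binary_target(60, seed = 64)
  pk <- mann_whitney_rank(mnull, ynull)$p_value
  expect_gt(suppressWarnings(stats::ks.test(pk, "punif")$p.value), 0.01)
})

test_that("cross-validation produces one clean estimate per split", {
  d <- make_planted(p = 12, n = 50, planted = 1:2, effect = 10, seed = 65)
  cv <- cross_validate(d$m, d$y, learner_majority(), n_folds = 10,
                       n_repeats = 10, seed = 7)
  expect_equal(nrow(cv$values), 100)

  # folds partition the samples within each repeat
  for (r in seq_len(10)) {
    expect_setequal(unique(cv$folds[[r]]), 1:10)
    expect_length(cv$folds[[r]], 50)
  }

  # stratification: class proportions preserved within +/- 1 sample
  ypos <- btrsign:::positive_mask(d$y)
  for (f in 1:10) {
    npos_f <- sum(ypos[cv$folds[[1]] == f])
    expect_true(abs(npos_f - sum(ypos) / 10) <= 1)
  }

  # majority baseline reproduces the majority-class proportion
  ymaj <- make_binary_target(50, n_pos = 15, seed = 66,
                             ids = sample_ids(d$m))
  cvm <- cross_validate(d$m, ymaj, learner_majority(), n_folds = 5,
                        n_repeats = 2, seed = 8)
  expect_equal(mean(cvm$values$value), 0.7, tolerance = 0.02)

  # same seed -> identical splits
  cv2 <- cross_validate(d$m, d$y, learner_majority(), n_folds = 10,
                        n_repeats = 10, seed = 7)
  expect_identical(cv$folds, cv2$folds)

  ytiny <- make_binary_target(50, n_pos = 3, seed = 67, ids = sample_ids(d$m))
  expect_error(cross_validate(d$m, ytiny, learner_majority(), n_folds = 5),
               class = "btr_validation_error")
})

test_that("comparator adapters fit and predict through the shared contract", {
  d <- make_planted(p = 15, n = 60, planted = 1:2, effect = 12, seed = 68)
  for (lrn in list(learner_enet(k_top = 5), learner_rf(k_top = 5, ntree = 60),
                   learner_svm(k_top = 5))) {
    cv <- cross_validate(d$m, d$y, lrn, n_folds = 3, n_repeats = 1, seed = 3)
    expect_equal(nrow(cv$values), 3)
    # a strongly planted signal is learnable by every comparator
    expect_gt(mean(cv$values$value), 0.7)
  }
})

test_that("comparators fall back to the majority rule on zero-variance folds", {
  v <- matrix(rep(seq(0.2, 2, length.out = 8), 20), 8, 20,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%02d", 1:20)))
  m <- btrsign:::new_abundance(v, "relative")
  y <- make_binary_target(20, n_pos = 7, seed = 69, ids = sample_ids(m))
  for (lrn in list(learner_enet(), learner_rf(), learner_svm())) {
    fitted <- lrn$fit(m, y)
    pred <- lrn$predict(fitted, m)
    expect_true(all(pred$labels == "neg"))   # training majority
  }
})

test_that("paired comparison verdicts follow the t-test and its edge cases", {
  vals <- function(x) data.frame(repeat_ = 1, fold = seq_along(x), value = x)
  mk <- function(x, seed = 1) cv_result("l", vals(x), length(x), 1, "accuracy", seed)
  a <- mk(c(0.7, 0.8, 0.9, 0.6, 0.75))

  expect_equal(compare_learners(a, a)$verdict, "equivalent")
  expect_equal(compare_learners(a, a)$t, 0)

  b <- mk(c(0.7, 0.8, 0.9, 0.6, 0.75) - 0.1)
  cc <- compare_learners(a, b)
  expect_equal(cc$verdict, "a_better")
  expect_equal(cc$p_value, 0)

  set.seed(9)
  c1 <- mk(stats::runif(30, 0.6, 0.9))
  c2 <- mk(c1$values$value + stats::rnorm(30, 0.15, 0.01))
  expect_equal(compare_learners(c2, c1)$verdict, "a_better")
  expect_equal(compare_learners(c1, c2)$verdict, "b_better")

  expect_error(compare_learners(a, mk(stats::runif(5), seed = 2)),
               class = "btr_validation_error")
})
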