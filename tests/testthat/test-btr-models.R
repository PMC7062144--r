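test_that("scores follow the language semantics", {
  v <- matrix(c(0.10, 0.05, 0.08, 0.77,
                0.40, 0.10, 0.10, 0.40), 4, 2,
              dimnames = list(c("f1", "f2", "f3", "f4"), c("s1", "s2")))
  m <- abundance_matrix(v, "relative")

  ter <- btr_model("ter", c("f1", "f2", "f3"), c(1, 1, -1), "relative")
  expect_equal(unname(score_samples(ter, m)["s1"]), 0.07)

  ratio <- btr_model("ratio", c("f1", "f2", "f3"), c(1, -1, -1), "relative")
  expect_equal(unname(score_samples(ratio, m)["s2"]), 2.0)

  # two-species cumulated abundance of 0.08 falls under a 9.7% cut:
  # classified on the low-score side
  bin <- btr_model("bin", c("f2", "f3"), c(1, 1), "relative",
                   threshold = 0.097, direction = "score_less",
                   class_map = list(positive = "healthy", negative = "disease"))
  expect_equal(unname(score_samples(bin, m)["s1"]), 0.13)
  expect_equal(unname(score_samples(bin, m)["s2"]), 0.2)
  m08 <- abundance_matrix(matrix(c(0.05, 0.03, 0.6, 0.32), 4, 1,
    dimnames = list(c("f1", "f2", "f3", "f4"), "s1")), "relative")
  sc <- score_samples(btr_model("bin", c("f1", "f2"), c(1, 1), "relative"), m08)
  expect_equal(unname(sc), 0.08)
  expect_true(sc < 0.097)

  missing <- btr_model("bin", "nope", 1, "relative")
  expect_error(score_samples(missing, m), class = "btr_validation_error")
  expect_error(score_samples(ter, to_presence(m)), class = "btr_validation_error")
})

test_that("ratio sentinels keep predictions defined on sparse data", {
  v <- rbind(f1 = c(0.5, 0, 0.2),
             f2 = c(0, 0, 0),
             f3 = c(0.2, 0.3, 0.5))
  colnames(v) <- c("s1", "s2", "s3")
  m <- btrsign:::new_abundance(v, "relative")
  ratio <- btr_model("ratio", c("f1", "f2"), c(1, -1), "relative",
                     threshold = 81, direction = "score_greater",
                     class_map = list(positive = "healthy", negative = "disease"))
  sc <- score_samples(ratio, m)
  expect_equal(unname(sc), c(Inf, 0, Inf))  # x/0, 0/0 -> 0, x/0
  pr <- predict(ratio, m)
  expect_equal(unname(pr), c("healthy", "disease", "healthy"))
})

test_that("a ratio factor of 81 separates samples as stated", {
  # one numerator species 82x / 80x the cumulated denominator abundance
  v <- matrix(c(82, 0.6, 0.4, 17,
                80, 0.6, 0.4, 19), 4, 2,
              dimnames = list(c("num", "d1", "d2", "other"), c("sA", "sB")))
  m <- btrsign:::new_abundance(sweep(v, 2, colSums(v), "/"), "relative")
  ratio <- btr_model("ratio", c("num", "d1", "d2"), c(1, -1, -1), "relative",
                     threshold = 81, direction = "score_greater",
                     class_map = list(positive = "healthy", negative = "disease"))
  expect_equal(unname(predict(ratio, m)), c("healthy", "disease"))
})

test_that("prediction ties go to the non-positive class", {
  v <- matrix(c(0.3, 0.7, 0.5, 0.5), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  m <- abundance_matrix(v, "relative")
  bin <- btr_model("bin", "f1", 1, "relative", threshold = 0.5,
                   direction = "score_greater",
                   class_map = list(positive = "pos", negative = "neg"))
  expect_equal(unname(predict(bin, m)), c("neg", "neg"))  # 0.3 < 0.5, 0.5 == 0.5
  bin$direction <- "score_less"
  expect_equal(unname(predict(bin, m)), c("pos", "neg"))
  bin$class_map <- NULL
  expect_error(predict(bin, m), class = "btr_validation_error")
})

test_that("model construction enforces language invariants", {
  expect_error(btr_model("bin", c("a", "b"), c(1, -1), "relative"),
               class = "btr_validation_error")
  expect_error(btr_model("ratio", c("a", "b"), c(-1, -1), "relative"),
               class = "btr_validation_error")  # empty numerator
  expect_error(btr_model("terlog", "a", 1, "relative"),
               class = "btr_validation_error")  # terlog needs log scale
  expect_error(btr_model("ter", character(0), numeric(0), "relative"),
               class = "btr_validation_error")  # k >= 1
  expect_silent(btr_model("terlog", "a", 1, "log"))
})

test_that("optimize_threshold handles the worked examples", {
  sep <- optimize_threshold(c(0.1, 0.2, 0.8, 0.9), c("neg", "neg", "pos", "pos"))
  expect_equal(sep$threshold, 0.5)
  expect_equal(sep$direction, "score_greater")
  expect_equal(sep$train_error, 0L)

  mid <- optimize_threshold(c(0.1, 0.2, 0.3, 0.4), c("neg", "pos", "pos", "neg"))
  expect_equal(mid$train_error,
               brute_force_threshold(c(0.1, 0.2, 0.3, 0.4),
                                     c(FALSE, TRUE, TRUE, FALSE)))
  expect_equal(mid$train_error, 1L)

  const <- optimize_threshold(rep(2, 5), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(const$train_error, 1L)  # min class count

  expect_error(optimize_threshold(c(1, 2), c(TRUE, TRUE)),
               class = "btr_validation_error")
  expect_error(optimize_threshold(1, TRUE), class = "btr_validation_error")
})

test_that("optimize_threshold matches brute force on random instances", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(2:50, 1)
    sc <- round(stats::rnorm(n), sample(0:2, 1))
    if (stats::runif(1) < 0.15) sc[sample(n, 1)] <- Inf
    yp <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(yp) || !any(yp)) next
    res <- optimize_threshold(sc, yp)
    expect_identical(res$train_error, brute_force_threshold(sc, yp))
    # the returned cut must itself achieve the reported error
    pred <- if (res$direction == "score_greater") sc > res$threshold
            else sc < res$threshold
    expect_equal(sum(pred != yp), res$train_error)
  }
})

test_that("fit_model_threshold separates a planted signal and is stable", {
  d <- make_planted(p = 10, n = 40, planted = 1:2, effect = 50, seed = 21)
  mod <- btr_model("bin", c("f001", "f002"), c(1, 1), "relative")
  fit1 <- fit_model_threshold(mod, d$m, d$y)
  expect_equal(fit1$fitness$value, 1.0)
  expect_equal(unname(predict(fit1, d$m)), unname(d$y$values))
  fit2 <- fit_model_threshold(fit1, d$m, d$y)
  expect_identical(fit2$threshold, fit1$threshold)
  expect_identical(fit2$direction, fit1$direction)

  # for ratio models the fitted cut IS the optimum of the ratio scores
  rmod <- btr_model("ratio", c("f001", "f003"), c(1, -1), "relative")
  rfit <- fit_model_threshold(rmod, d$m, d$y)
  opt <- optimize_threshold(score_samples(rmod, d$m), d$y)
  expect_identical(rfit$threshold, opt$threshold)
  expect_identical(rfit$direction, opt$direction)
})

test_that("bin/ter scores equal constrained full-length linear models", {
  m <- make_abundance(12, 15, seed = 31)
  ter <- btr_model("ter", c("f002", "f005", "f009"), c(1, -1, 1), "relative")
  beta <- numeric(12)
  names(beta) <- feature_ids(m)
  beta[ter$features] <- ter$coefficients
  expect_equal(unname(score_samples(ter, m)),
               unname(drop(beta %*% m$values)))
  # decision monotonicity of bin models: raising a selected feature never
  # flips a sample to the negative side under score_greater
  bin <- btr_model("bin", c("f001", "f004"), c(1, 1), "relative",
                   threshold = 0.1, direction = "score_greater",
                   class_map = list(positive = "pos", negative = "neg"))
  pr0 <- predict(bin, m)
  m2 <- m
  m2$values["f001", ] <- m2$values["f001", ] + 0.5
  m2 <- btrsign:::new_abundance(m2$values, "relative")
  pr1 <- predict(bin, m2)
  expect_true(all(!(pr0 == "pos" & pr1 == "neg")))
})

test_that("regression scaling recovers exact linear maps and degenerates cleanly", {
  set.seed(41)
  sc <- stats::rnorm(50)
  y <- 2 * sc + 1
  fit <- fit_regression_scaling(sc, y, metric = "r2")
  expect_equal(fit$alpha, 2, tolerance = 1e-12)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_equal(fit$value, 1, tolerance = 1e-12)

  # OLS equivariance: scaling the target scales alpha and beta
  fit3 <- fit_regression_scaling(sc, 3 * y)
  expect_equal(fit3$alpha, 3 * fit$alpha, tolerance = 1e-12)
  expect_equal(fit3$beta, 3 * fit$beta, tolerance = 1e-12)

  # independent target: Spearman rho near zero at n = 100
  set.seed(42)
  s2 <- stats::rnorm(100)
  yperm <- sample(2 * s2 + 1)
  rho <- fit_regression_scaling(s2, yperm, metric = "spearman_rho")$value
  expect_lt(abs(rho), 0.2)

  expect_error(fit_regression_scaling(rep(1, 10), stats::rnorm(10)),
               class = "btr_degenerate_error")
  expect_error(fit_regression_scaling(c(1, 2), c(1, 2)),
               class = "btr_validation_error")
})
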