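test_that("abundance tables round-trip through TSV with validation", {
  m <- make_abundance(3, 2, seed = 10, scale = "raw")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(m, path)
  m2 <- read_abundance_table(path)
  expect_s3_class(m2, "btr_abundance")
  expect_equal(dim(m2$values), c(3, 2))
  expect_equal(m2$scale, "raw")
  expect_equal(m2$values, m$values, tolerance = 1e-9)
  expect_equal(feature_ids(m2), feature_ids(m))

  # byte-stable writes
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(m2, path2)
  expect_identical(readLines(path), readLines(path2))

  # orientation flag
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t1\t2", "s2\t3\t4"), path3)
  mt <- read_abundance_table(path3, features_in_rows = FALSE)
  expect_equal(feature_ids(mt), c("f1", "f2"))
  expect_equal(unname(mt$values["f2", "s1"]), 2)
})

test_that("malformed tables are rejected with located errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "fA\t1\t2", "fA\t3\t4"), dup)
  expect_error(read_abundance_table(dup), class = "btr_validation_error")
  expect_error(read_abundance_table(dup), "fA")

  na <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "fA\t1\tNA", "fB\t3\t4"), na)
  err <- tryCatch(read_abundance_table(na), error = identity)
  expect_s3_class(err, "btr_parse_error")
  expect_match(conditionMessage(err), "fA")
  expect_match(conditionMessage(err), "s2")
})

test_that("normalize_relative closes columns and is a fixed point", {
  v <- matrix(c(2, 3, 5, 1, 1, 2), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- normalize_relative(abundance_matrix(v, "raw"))
  expect_equal(unname(m$values[, "s1"]), c(0.2, 0.3, 0.5))
  expect_equal(m$scale, "relative")
  m2 <- normalize_relative(m)
  expect_equal(m2$values, m$values, tolerance = 1e-12)

  neg <- abundance_matrix(matrix(c(-1, 2), 2, 1,
    dimnames = list(c("a", "b"), "s1")), "raw")
  expect_error(normalize_relative(neg), class = "btr_domain_error")

  zero <- abundance_matrix(matrix(c(1, 1, 0, 0), 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))), "raw")
  err <- tryCatch(normalize_relative(zero), error = identity)
  expect_s3_class(err, "btr_degenerate_error")
  expect_match(conditionMessage(err), "s2")
})

test_that("to_presence binarizes, is idempotent and commutes with subsetting", {
  v <- matrix(c(0, 0.001, 0.5, 0, 0, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- abundance_matrix(v, "raw")
  pr <- to_presence(m)
  expect_equal(unname(pr$values[, "s1"]), c(0, 1, 1))
  expect_equal(pr$scale, "presence")
  expect_identical(to_presence(pr)$values, pr$values)
  # all-zero feature rows are retained
  expect_true(all(pr$values["a", ] == 0))

  big <- make_abundance(10, 20, seed = 4)
  sub <- sample(20, 8)
  a <- to_presence(btrsign:::subset_samples(big, sub))
  b <- btrsign:::subset_samples(to_presence(big), sub)
  expect_identical(a$values, b$values)
})

test_that("log_transform is monotone, offsets zeros, and rejects bad pseudocounts", {
  v <- matrix(c(0, 0.3, 0.7, 0.2, 0.5, 0.3), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- abundance_matrix(v, "raw")
  lg <- log_transform(m, pseudocount = 1e-6)
  expect_equal(unname(lg$values["a", "s1"]), log(1e-6))
  expect_equal(lg$scale, "log")
  # monotone
  x <- sort(stats::runif(20))
  ord <- order(log(x + 1e-6))
  expect_equal(ord, seq_along(x))
  expect_error(log_transform(m, pseudocount = 0), class = "btr_domain_error")
})

test_that("SD-elbow filter separates a two-cluster SD mixture", {
  set.seed(42)
  n <- 30
  low <- matrix(stats::rnorm(50 * n, mean = 1, sd = 0.001), 50, n)
  high <- matrix(stats::rnorm(50 * n, mean = 1, sd = 0.1), 50, n)
  v <- rbind(low, high)
  dimnames(v) <- list(sprintf("f%03d", 1:100), sprintf("s%02d", 1:n))
  m <- abundance_matrix(v, "raw")
  res <- filter_low_sd(m)
  expect_setequal(res$removed, sprintf("f%03d", 1:50))
  expect_equal(nrow(res$matrix$values), 50)

  # independent verification that the elbow lands between the clusters:
  # the maximum central second difference of the sorted SD curve sits at the
  # top of the low cluster
  sds <- sort(apply(v, 1, stats::sd))
  d2 <- sds[-(1:2)] - 2 * sds[-c(1, 100)] + sds[-(99:100)]
  elbow <- which.max(d2) + 1
  expect_true(sds[elbow] < min(apply(high, 1, stats::sd)))
  expect_true(sds[elbow] >= max(apply(low, 1, stats::sd)) - 1e-12)
})

test_that("SD filter degenerate cases: constants, flat curves", {
  v <- matrix(stats::rnorm(5 * 10), 5, 10,
              dimnames = list(sprintf("f%d", 1:5), sprintf("s%d", 1:10)))
  v[3, ] <- 7   # constant feature
  res <- filter_low_sd(abundance_matrix(v, "raw"))
  expect_true("f3" %in% res$removed)

  # identical nonzero SDs: flat curve, nothing removed
  flat <- matrix(0, 4, 4, dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:4)))
  for (i in 1:4) flat[i, ] <- c(0, 1, 0, 1) + i   # same SD per row
  res2 <- filter_low_sd(abundance_matrix(flat, "raw"))
  expect_length(res2$removed, 0)

  allconst <- matrix(1, 3, 4, dimnames = list(sprintf("f%d", 1:3), sprintf("s%d", 1:4)))
  expect_error(filter_low_sd(abundance_matrix(allconst, "raw")),
               class = "btr_degenerate_error")

  # never removes a feature whose SD exceeds that of a retained feature
  set.seed(7)
  for (rep in 1:20) {
    mm <- make_abundance(15, 12, seed = rep, scale = "raw")
    out <- tryCatch(filter_low_sd(mm), btr_degenerate_error = function(e) NULL)
    if (is.null(out) || length(out$removed) == 0) next
    sds <- apply(mm$values, 1, stats::sd)
    expect_lt(max(sds[out$removed]), min(sds[setdiff(names(sds), out$removed)]) + 1e-15)
  }
})

test_that("sample targets validate and read from metadata files", {
  expect_error(sample_target(c("a", "b", "c"), c("s1", "s2", "s3")),
               class = "btr_validation_error")  # 3 classes
  y <- sample_target(c("hc", "ill", "hc"), c("s1", "s2", "s3"))
  expect_equal(y$positive_class, "ill")  # lexicographically larger default
  expect_equal(y$kind, "binary_class")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttarget", "s1\t0.5", "s2\t1.5", "s3\t2.5"), path)
  yc <- read_sample_target(path)
  expect_equal(yc$kind, "continuous")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\ta"), bad)
  expect_error(read_sample_target(bad), class = "btr_config_error")
})
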