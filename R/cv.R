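#' Construct a cross-validation result
#'
#' Container for per-split generalization estimates of one learner. Usually
#' produced by [cross_validate()]; the constructor is exported so that
#' externally computed per-split values can be fed to [compare_learners()].
#'
#' @param learner_name Name of the learner.
#' @param values Data frame with columns `repeat_`, `fold`, `value`
#'   (one row per CV split, `n_folds * n_repeats` rows).
#' @param n_folds,n_repeats CV scheme.
#' @param metric Metric name of the stored values.
#' @param seed Seed that generated the fold assignments.
#' @param folds List (one element per repeat) of integer fold assignments.
#' @param fits Optional list of per-split fit artifacts (selected model,
#'   FBM, test sample indices) for BTR learners.
#' @return An object of class `btr_cv`.
#' @export
cv_result <- function(learner_name, values, n_folds, n_repeats, metric,
                      seed, folds = NULL, fits = NULL) {
  if (!all(c("repeat_", "fold", "value") %in% colnames(values)))
    btr_validation_error("'values' needs columns repeat_, fold, value")
  if (nrow(values) != n_folds * n_repeats)
    btr_validation_error("number of stored values must equal n_folds * n_repeats")
  structure(list(learner_name = learner_name, values = values,
                 n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 metric = metric, seed = seed, folds = folds, fits = fits),
            class = "btr_cv")
}

#' @method print btr_cv
#' @export
print.btr_cv <- function(x, ...) {
  cat(sprintf("<btr_cv> %s: %d-fold x %d repeats, %s = %.4f +/- %.4f (SEM)\n",
              x$learner_name, x$n_folds, x$n_repeats, x$metric,
              mean(x$values$value),
              stats::sd(x$values$value) / sqrt(nrow(x$values))))
  invisible(x)
}

# stratified fold assignment: class proportions preserved within +/- 1 sample
make_folds <- function(ypos, n_folds, n_repeats) {
  n <- length(ypos)
  lapply(seq_len(n_repeats), function(r) {
    assign <- integer(n)
    for (cls in unique(ypos)) {
      idx <- sample(which(ypos == cls))
      assign[idx] <- rep_len(sample(n_folds), length(idx))
    }
    assign
  })
}

#' Repeated stratified cross-validation of a learner
#'
#' Estimates the generalization performance of a learner by `n_repeats`
#' rounds of stratified `n_folds`-fold cross-validation (the classification
#' default, 10 x 10, yields 100 estimates; 20 x 5 is the regression
#' convention). Every data-dependent step -- SD filtering, Mann-Whitney
#' ranking, threshold fitting -- happens inside the learner's `fit` on the
#' training folds only, so the estimates are leak-free. Fold assignments are
#' deterministic given `seed` and depend only on the labels and the scheme,
#' so different learners run with the same seed see identical splits and can
#' be compared pairwise.
#'
#' @param m A `btr_abundance`.
#' @param y A `btr_target` (binary for classification learners).
#' @param learner A learner adapter, e.g. [learner_btr()].
#' @param n_folds Folds per repeat (every class needs at least `n_folds`
#'   samples).
#' @param n_repeats Repeats.
#' @param metric Test metric, default `"accuracy"`.
#' @param seed Integer seed for the fold assignments.
#' @return A [cv_result()].
#' @export
cross_validate <- function(m, y, learner, n_folds = 10, n_repeats = 10,
                           metric = "accuracy", seed = 42) {
  if (!inherits(learner, "btr_learner")) btr_validation_error("'learner' must be a btr_learner")
  y <- align_target(y, m)
  n <- n_samples(m)
  if (n < n_folds) btr_validation_error("fewer samples than folds")
  strata <- if (y$kind == "binary_class") y$values else rep("all", n)
  if (min(table(strata)) < n_folds && y$kind == "binary_class")
    btr_validation_error("a class has fewer samples than folds: stratification impossible")
  set.seed(seed)
  folds <- make_folds(strata, n_folds, n_repeats)
  rows <- vector("list", n_folds * n_repeats)
  fits <- vector("list", n_folds * n_repeats)
  s <- 0L
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(n_folds)) {
      s <- s + 1L
      te <- which(folds[[r]] == f)
      tr <- which(folds[[r]] != f)
      m_tr <- subset_samples(m, tr)
      m_te <- subset_samples(m, te)
      fitted <- learner$fit(m_tr, subset_target(y, tr))
      y_te <- subset_target(y, te)
      pred <- learner$predict(fitted, m_te)
      val <- if (metric == "auc") {
        compute_metric(y_te, pred$scores, "auc")
      } else if (metric %in% c("r2", "spearman_rho", "ser")) {
        compute_metric(unname(y_te$values), pred$predictions, metric)
      } else {
        compute_metric(y_te, pred$labels, metric)
      }
      rows[[s]] <- data.frame(repeat_ = r, fold = f, value = val)
      fits[[s]] <- list(model = fitted$model %||% NULL,
                        fbm = fitted$fbm %||% NULL, test_idx = te)
    }
  }
  cv_result(learner$name, do.call(rbind, rows), n_folds, n_repeats, metric,
            seed, folds = folds, fits = fits)
}

#' Compare two learners with a paired t-test over CV splits
#'
#' Applies a paired t-test to the per-split differences of two
#' cross-validation results obtained on identical splits (same scheme, seed
#' and fold assignments). Learners whose difference is not significant at
#' `p_level` are considered equivalent. Paired differences that are all
#' exactly zero give the `equivalent` verdict directly; a constant nonzero
#' difference is reported as significant with the sign of the difference.
#'
#' @param a,b `btr_cv` objects from [cross_validate()] with matching splits.
#' @param p_level Significance level (default 0.05).
#' @return List with `t`, `p_value`, `mean_difference`, `verdict`
#'   (`"a_better"`, `"b_better"` or `"equivalent"`).
#' @export
compare_learners <- function(a, b, p_level = 0.05) {
  if (a$n_folds != b$n_folds || a$n_repeats != b$n_repeats || a$seed != b$seed)
    btr_validation_error("CV results use different schemes or seeds")
  if (!is.null(a$folds) && !is.null(b$folds) && !identical(a$folds, b$folds))
    btr_validation_error("CV results use different fold assignments")
  d <- a$values$value - b$values$value
  md <- mean(d)
  if (stats::sd(d) == 0) {
    if (md == 0) {
      return(list(t = 0, p_value = 1, mean_difference = 0, verdict = "equivalent"))
    }
    return(list(t = sign(md) * Inf, p_value = 0, mean_difference = md,
                verdict = if (md > 0) "a_better" else "b_better"))
  }
  tt <- stats::t.test(d)
  verdict <- if (tt$p.value >= p_level) "equivalent"
             else if (md > 0) "a_better" else "b_better"
  list(t = unname(tt$statistic), p_value = tt$p.value, mean_difference = md,
       verdict = verdict)
}

#' Write per-split CV values as TSV
#'
#' @param cv A `btr_cv`.
#' @param path Output path.
#' @export
write_cv_tsv <- function(cv, path) {
  df <- data.frame(learner = cv$learner_name,
                   split_id = seq_len(nrow(cv$values)),
                   repeat_ = cv$values$repeat_, fold = cv$values$fold,
                   metric = cv$metric, value = sprintf("%.10g", cv$values$value))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
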