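#' Compute a classification or regression metric
#'
#' Classification metrics (`accuracy`, `f1`, `precision`, `recall`) take
#' predicted labels; `auc` takes scores oriented so that higher values favor
#' the positive class and is computed as the Mann-Whitney rank statistic
#' (ties get mean ranks, so all-equal scores give AUC 0.5). Regression
#' metrics (`r2`, `spearman_rho`, `ser`) take predicted values; `ser` is the
#' residual standard error divided by the target's standard deviation.
#'
#' @param y_true Observed labels (or numeric targets), possibly a
#'   `btr_target`.
#' @param y_pred Predicted labels, scores (for `auc`), or numeric
#'   predictions.
#' @param metric Metric name.
#' @param positive_class Positive label for `f1`/`precision`/`recall`/`auc`;
#'   defaults to the target's positive class or the lexicographically larger
#'   label.
#' @return A single number.
#' @export
compute_metric <- function(y_true, y_pred,
                           metric = c("accuracy", "auc", "f1", "precision",
                                      "recall", "r2", "spearman_rho", "ser"),
                           positive_class = NULL) {
  metric <- match.arg(metric)
  if (inherits(y_true, "btr_target")) {
    if (is.null(positive_class)) positive_class <- y_true$positive_class
    y_true <- unname(y_true$values)
  }
  if (length(y_true) != length(y_pred))
    btr_validation_error("y_true and y_pred lengths differ")

  if (metric %in% c("r2", "spearman_rho", "ser")) {
    resid <- y_true - y_pred
    return(switch(metric,
      r2 = stats::cor(y_true, y_pred)^2,
      spearman_rho = stats::cor(y_true, y_pred, method = "spearman"),
      ser = sqrt(sum(resid^2) / max(1, length(y_true) - 2)) / stats::sd(y_true)))
  }

  if (metric == "auc") {
    pos <- as_positive_mask(y_true, positive_class)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0)
      btr_degenerate_error("AUC is undefined when only one class is present")
    r <- rank(y_pred)
    return((sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }

  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (metric == "accuracy") return(mean(y_true == y_pred))

  if (is.null(positive_class)) {
    lev <- sort(unique(y_true))
    positive_class <- lev[length(lev)]
  }
  tp <- sum(y_pred == positive_class & y_true == positive_class)
  fp <- sum(y_pred == positive_class & y_true != positive_class)
  fn <- sum(y_pred != positive_class & y_true == positive_class)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  switch(metric,
    precision = precision,
    recall = recall,
    f1 = if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall))
}

#' Rank features by Mann-Whitney association with a binary class
#'
#' Per feature, computes the Mann-Whitney U statistic of the positive-class
#' samples, the tie-corrected normal-approximation two-sided p-value, and
#' the enrichment direction (class with the greater mean rank). Features are
#' ordered by ascending p-value, with ties resolved by the distance of
#' `U/(n1*n2)` from 0.5 (descending) and then by feature name. The ranking
#' is used to pre-select features for the comparator learners and to seed
#' the genetic search.
#'
#' @param m A `btr_abundance`.
#' @param y Binary `btr_target`.
#' @return A data frame with columns `feature`, `U`, `auc` (`U/(n1*n2)`),
#'   `p_value`, `direction` (+1 = higher in positive class), in rank order.
#' @export
mann_whitney_rank <- function(m, y) {
  y <- align_target(y, m)
  pos <- positive_mask(y)
  n1 <- sum(pos); n0 <- sum(!pos); n <- n1 + n0
  X <- m$values
  res <- vapply(seq_len(nrow(X)), function(i) {
    r <- rank(X[i, ])
    u <- sum(r[pos]) - n1 * (n1 + 1) / 2
    ties <- table(X[i, ])
    tiecor <- sum(ties^3 - ties)
    sig2 <- n1 * n0 / 12 * ((n + 1) - tiecor / (n * (n - 1)))
    p <- if (sig2 <= 0) 1 else 2 * stats::pnorm(-abs(u - n1 * n0 / 2) / sqrt(sig2))
    c(u, min(1, p))
  }, numeric(2))
  auc <- res[1, ] / (n1 * n0)
  df <- data.frame(feature = feature_ids(m), U = res[1, ], auc = auc,
                   p_value = res[2, ],
                   direction = ifelse(auc >= 0.5, 1L, -1L),
                   stringsAsFactors = FALSE)
  df <- df[order(df$p_value, -abs(df$auc - 0.5), df$feature), , drop = FALSE]
  rownames(df) <- NULL
  df
}
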